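# Shared evaluation core: one environment, one set of stochastic sojourns,
# both strategies. The same walk influx sequences feed the induced model
# (possibly several parameter variants, e.g. a gamma or delta scan) and the
# constitutive grid search, so strategy comparisons are paired and scan
# variants differ only through the parameters.
env_strategy_fitness <- function(env, induced_params, k0, walk_cfg,
                                 grid = seq(0.01, 2, by = 0.01),
                                 weights = fitness_weights(),
                                 integrator = integrator_config()) {
  if (inherits(induced_params, "imd_params")) {
    induced_params <- list(induced_params)
  }
  spec <- attr(env, "spec")
  cm <- env_count_matrix(env)
  t_total <- walk_cfg$n_steps * walk_cfg$dt_per_step
  cfg_i <- integrator
  cfg_i$t_end <- t_total
  n_var <- length(induced_params)
  ind_fit <- matrix(NA_real_, walk_cfg$n_walks, n_var)
  const_fit <- matrix(NA_real_, walk_cfg$n_walks, length(grid))
  for (w in seq_len(walk_cfg$n_walks)) {
    influx <- walk_influx(cm, spec$size, walk_cfg, w)$influx
    inp <- piecewise_input(influx, walk_cfg$dt_per_step)
    for (v in seq_len(n_var)) {
      res <- induced_means(induced_params[[v]], inp, cfg_i)
      ind_fit[w, v] <- if (res$blown) NA_real_ else
        fitness_induced(res$means, weights)
    }
    bbar <- const_bbar_grid_cpp(influx, walk_cfg$dt_per_step, k0, grid, 0)
    const_fit[w, ] <- exp(-(weights$weight_B * bbar +
                              weights$weight_A * grid))
  }
  curve <- tibble(A = grid, fitness = colMeans(const_fit))
  best <- which.max(curve$fitness)
  list(F_induced = colMeans(ind_fit),
       curve = curve,
       A_opt = curve$A[best],
       F_constitutive = curve$fitness[best])
}

# params variant helpers used by the scans
with_k0 <- function(params, k0) { params$k0 <- k0; validate_imd_params(params); params }
scale_feedback <- function(params, gamma) {
  params$beta3 <- params$beta3 * gamma
  params$beta4 <- params$beta4 * gamma
  validate_imd_params(params)
  params
}
scale_zs <- function(params, delta) {
  params$Zs <- params$Zs * delta
  validate_imd_params(params)
  params
}

as_imd_params <- function(x) {
  if (inherits(x, "imd_opt")) {
    if (x$strategy != "induced") abort("need an induced strategy")
    x$params
  } else if (inherits(x, "imd_params")) {
    x
  } else {
    abort("expected an imd_params or induced imd_opt")
  }
}

#' Fitness of both strategies over a density-by-patchiness grid
#'
#' For every (density, patchiness) cell: generates one environment, runs
#' `walk_cfg$n_walks` stochastic sojourns, and records the mean per-walk
#' fitness of the induced strategy alongside the grid-search-optimal
#' constitutive strategy for that environment (both facing the same
#' walks). This is the heat-map experiment from which the proportion of
#' induced wins is read off.
#'
#' @param induced an induced [optimize_induced()] result or an
#'   [imd_params()] (its `k0` is replaced by `k0` below, so both
#'   strategies face the same bacteria).
#' @param k0 bacterial proliferation rate of the tested environments.
#' @param densities,patchiness_levels grid axes. Patchiness entries larger
#'   than a density are clamped to it.
#' @param walk_cfg a [walk_config()] (its seed is ignored; per-cell seeds
#'   derive from `seed`).
#' @param size,cluster_sd lattice geometry passed to [environment_spec()].
#' @param grid AMP grid for the constitutive search.
#' @param weights a [fitness_weights()].
#' @param integrator an [integrator_config()].
#' @param seed global seed; per-cell environment and walk seeds are
#'   derived with [child_seed()].
#' @return A tibble of class `fitness_grid`: one row per cell with
#'   `density`, `patchiness`, `F_induced`, `F_constitutive`, `A_opt`,
#'   `delta_F` (= `F_constitutive - F_induced`), with provenance attached.
#' @export
run_fitness_grid <- function(induced, k0, densities, patchiness_levels,
                             walk_cfg = walk_config(), size = 100,
                             cluster_sd = 3,
                             grid = seq(0.01, 2, by = 0.01),
                             weights = fitness_weights(),
                             integrator = integrator_config(), seed = 1) {
  params <- with_k0(as_imd_params(induced), k0)
  cells <- tidyr::expand_grid(density = densities,
                              patchiness = patchiness_levels)
  rows <- purrr::pmap(cells, function(density, patchiness) {
    p_eff <- min(patchiness, max(density, 1))
    if (density == 0) {
      # no colonies: the induced pathway never fires (fitness 1) and any
      # standing AMP is pure cost, so the grid floor wins
      return(tibble(density = density, patchiness = patchiness,
                    F_induced = 1,
                    F_constitutive = exp(-grid[1]), A_opt = grid[1]))
    }
    env <- generate_environment(environment_spec(
      size = size, density = density, patchiness = p_eff,
      cluster_sd = cluster_sd,
      seed = child_seed(seed, sprintf("env:%g:%g", density, patchiness))))
    wc <- walk_cfg
    wc$seed <- child_seed(seed, sprintf("walks:%g:%g", density, patchiness))
    ev <- env_strategy_fitness(env, params, k0, wc, grid, weights,
                               integrator)
    tibble(density = density, patchiness = patchiness,
           F_induced = ev$F_induced, F_constitutive = ev$F_constitutive,
           A_opt = ev$A_opt)
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::mutate(delta_F = .data$F_constitutive - .data$F_induced)
  attr(out, "provenance") <- list(
    k0 = k0, size = size, cluster_sd = cluster_sd, seed = seed,
    n_walks = walk_cfg$n_walks, n_steps = walk_cfg$n_steps,
    dose = walk_cfg$dose, params = unclass(params), weights = weights$mode)
  class(out) <- c("fitness_grid", class(out))
  out
}

#' Proportion of induced wins
#'
#' The fraction of environments (grid cells, or entries of a win/loss
#' vector) in which the induced strategy's fitness strictly exceeds the
#' constitutive strategy's; ties count as constitutive wins.
#'
#' @param x a `fitness_grid` (or any data frame with `F_induced` and
#'   `F_constitutive` columns), or a logical vector of induced wins.
#' @return Scalar in \[0, 1\].
#' @export
compute_piw <- function(x) {
  if (is.data.frame(x)) {
    if (!all(c("F_induced", "F_constitutive") %in% names(x))) {
      abort("need F_induced and F_constitutive columns")
    }
    x <- x$F_induced > x$F_constitutive
  }
  if (!is.logical(x) || length(x) == 0) {
    abort("compute_piw needs a non-empty grid or logical vector")
  }
  mean(x)
}

#' Precompute an environment pool for multi-environment sampling
#'
#' Evaluates the induced strategy's fitness and the full constitutive
#' fitness curve in each listed environment (shared walks per
#' environment), optionally keeping only environments where the
#' constitutive optimum beats induction — the pool from which fluctuating
#' multi-environment lifestyles are sampled.
#'
#' @inheritParams run_fitness_grid
#' @param cells a data frame with `density` and `patchiness` columns, one
#'   row per candidate environment.
#' @param constitutive_favored_only drop cells where induction already
#'   wins in isolation, so the pool isolates the fluctuation effect.
#' @return An `env_pool` list: `cells`, `F_induced` (vector), `curves`
#'   (grid-length x n_env matrix of constitutive fitness), `grid`.
#' @export
environment_pool <- function(induced, k0, cells,
                             walk_cfg = walk_config(), size = 100,
                             cluster_sd = 3,
                             grid = seq(0.01, 2, by = 0.01),
                             weights = fitness_weights(),
                             integrator = integrator_config(), seed = 1,
                             constitutive_favored_only = TRUE) {
  params <- with_k0(as_imd_params(induced), k0)
  stopifnot(all(c("density", "patchiness") %in% names(cells)))
  n <- nrow(cells)
  F_ind <- numeric(n)
  curves <- matrix(NA_real_, length(grid), n)
  for (i in seq_len(n)) {
    d <- cells$density[i]; p <- min(cells$patchiness[i], d)
    env <- generate_environment(environment_spec(
      size = size, density = d, patchiness = p, cluster_sd = cluster_sd,
      seed = child_seed(seed, sprintf("pool-env:%d", i))))
    wc <- walk_cfg
    wc$seed <- child_seed(seed, sprintf("pool-walks:%d", i))
    ev <- env_strategy_fitness(env, params, k0, wc, grid, weights,
                               integrator)
    F_ind[i] <- ev$F_induced
    curves[, i] <- ev$curve$fitness
  }
  keep <- rep(TRUE, n)
  if (constitutive_favored_only) {
    keep <- apply(curves, 2, max) >= F_ind
  }
  structure(list(cells = cells[keep, , drop = FALSE],
                 F_induced = F_ind[keep],
                 curves = curves[, keep, drop = FALSE],
                 grid = grid,
                 provenance = list(k0 = k0, seed = seed,
                                   n_walks = walk_cfg$n_walks,
                                   n_steps = walk_cfg$n_steps)),
            class = "env_pool")
}

#' PIW under fluctuation across multiple environments
#'
#' Repeatedly samples lifestyles from an environment pool and asks which
#' strategy wins. With `j` given, each repeat draws `j` environments
#' without replacement and visits them with equal probability: induced
#' fitness is the arithmetic mean of its per-environment fitness, while
#' the constitutive strategy must pick one AMP level for all of them — the
#' maximum over the grid of the mean fitness curve. With `q` given, each
#' repeat draws 2 environments visited with probabilities `q` and `1 - q`
#' and the same logic applies with weighted means. The returned PIW is the
#' fraction of repeats the induced strategy strictly wins.
#'
#' @param pool an [environment_pool()].
#' @param j number of environments per draw (mutually exclusive with `q`).
#' @param q weight of the first of two environments.
#' @param n_repeats number of resampling repeats.
#' @param seed RNG seed.
#' @return A one-row tibble: `piw`, `n_repeats`, `j`, `q`, `pool_size`.
#' @export
sample_multi_environment <- function(pool, j = NULL, q = NULL,
                                     n_repeats = 10000, seed = NULL) {
  stopifnot(inherits(pool, "env_pool"))
  n <- length(pool$F_induced)
  if (is.null(j) == is.null(q)) abort("give exactly one of j or q")
  if (!is.null(j) && (j < 1 || j > n)) {
    abort("j must be in [1, pool size]")
  }
  if (!is.null(q) && (q < 0 || q > 1)) abort("q must be in [0, 1]")
  if (!is.null(q) && n < 2) abort("two-environment mode needs a pool >= 2")
  body <- function() {
    wins <- logical(n_repeats)
    for (r in seq_len(n_repeats)) {
      if (!is.null(j)) {
        idx <- if (j == n) seq_len(n) else sample.int(n, j)
        f_ind <- mean(pool$F_induced[idx])
        f_con <- max(rowMeans(pool$curves[, idx, drop = FALSE]))
      } else {
        idx <- sample.int(n, 2)
        wgt <- c(q, 1 - q)
        f_ind <- sum(wgt * pool$F_induced[idx])
        f_con <- max(pool$curves[, idx, drop = FALSE] %*% wgt)
      }
      wins[r] <- f_ind > f_con
    }
    wins
  }
  wins <- if (is.null(seed)) body() else withr::with_seed(seed, body())
  tibble(piw = mean(wins), n_repeats = n_repeats,
         j = if (is.null(j)) NA_integer_ else as.integer(j),
         q = if (is.null(q)) NA_real_ else q,
         pool_size = n)
}

#' PIW as PGRP-LB and Pirk production is rescaled
#'
#' Multiplies the two input-side negative-feedback production rates
#' (`beta3` for PGRP-LB, `beta4` for Pirk) of an optimized induced
#' strategy by each value of `gamma` and recomputes the proportion of
#' induced wins over a density-by-patchiness grid for each bacterial
#' proliferation rate. All gamma variants face identical environments and
#' walks, so differences are attributable to the feedback strength alone.
#'
#' @inheritParams run_fitness_grid
#' @param base_params optimized induced strategy (`imd_opt` or
#'   [imd_params()]).
#' @param gamma_values positive multipliers applied to `beta3` and
#'   `beta4`.
#' @param k0_values bacterial proliferation rates to test.
#' @param cells data frame of `density`, `patchiness` environments.
#' @return A tibble `gamma` x `k0` with `piw`, carrying a `best` attribute
#'   (per-`k0` argmax gamma, ties toward the smaller gamma).
#' @export
gamma_scan <- function(base_params, gamma_values, k0_values, cells,
                       walk_cfg = walk_config(), size = 100, cluster_sd = 3,
                       grid = seq(0.01, 2, by = 0.01),
                       weights = fitness_weights(),
                       integrator = integrator_config(), seed = 1) {
  base <- as_imd_params(base_params)
  if (any(gamma_values <= 0)) abort("gamma values must be > 0")
  out <- purrr::map(k0_values, function(k0) {
    variants <- purrr::map(gamma_values,
                           ~ scale_feedback(with_k0(base, k0), .x))
    wins <- matrix(NA, nrow(cells), length(gamma_values))
    for (i in seq_len(nrow(cells))) {
      d <- cells$density[i]; p <- min(cells$patchiness[i], d)
      env <- generate_environment(environment_spec(
        size = size, density = d, patchiness = p, cluster_sd = cluster_sd,
        seed = child_seed(seed, sprintf("gamma-env:%g:%d", k0, i))))
      wc <- walk_cfg
      wc$seed <- child_seed(seed, sprintf("gamma-walks:%g:%d", k0, i))
      ev <- env_strategy_fitness(env, variants, k0, wc, grid, weights,
                                 integrator)
      wins[i, ] <- ev$F_induced > ev$F_constitutive
    }
    tibble(gamma = gamma_values, k0 = k0, piw = colMeans(wins))
  })
  out <- dplyr::bind_rows(out)
  best <- out |>
    dplyr::group_by(.data$k0) |>
    dplyr::slice_max(.data$piw, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select(k0 = "k0", best_gamma = "gamma", piw = "piw")
  attr(out, "best") <- best
  out
}

#' Best repressosome binding energy per environment
#'
#' Scales the repressosome binding energy `Zs` of an optimized induced
#' strategy by each `delta` (larger delta, weaker repression) and, in each
#' environment and at each proliferation rate, finds the delta maximizing
#' induced fitness (ties toward the smallest delta). Optionally rescales
#' the PGRP-LB/Pirk rates first (`gamma`), which is how the low-feedback
#' variant of the scan is run.
#'
#' @inheritParams gamma_scan
#' @param delta_values positive multipliers on `Zs`; must include 1.
#' @param gamma optional multiplier on `beta3`/`beta4` applied before the
#'   scan.
#' @return A list of class `delta_scan` with `per_environment` (one row
#'   per environment x k0: fitness at each delta and `best_delta`) and
#'   `counts` (environments per (k0, delta) whose maximum sits there).
#' @export
delta_scan <- function(base_params, delta_values = c(1, 2, 4, 10),
                       k0_values, cells, gamma = 1,
                       walk_cfg = walk_config(), size = 100, cluster_sd = 3,
                       weights = fitness_weights(),
                       integrator = integrator_config(), seed = 1) {
  base <- as_imd_params(base_params)
  if (!1 %in% delta_values) abort("delta_values must include 1")
  if (any(delta_values <= 0)) abort("delta values must be > 0")
  delta_values <- sort(delta_values)
  rows <- purrr::map(k0_values, function(k0) {
    variants <- purrr::map(
      delta_values, ~ scale_zs(scale_feedback(with_k0(base, k0), gamma), .x))
    purrr::map(seq_len(nrow(cells)), function(i) {
      d <- cells$density[i]; p <- min(cells$patchiness[i], d)
      env <- generate_environment(environment_spec(
        size = size, density = d, patchiness = p, cluster_sd = cluster_sd,
        seed = child_seed(seed, sprintf("delta-env:%g:%d", k0, i))))
      wc <- walk_cfg
      wc$seed <- child_seed(seed, sprintf("delta-walks:%g:%d", k0, i))
      # constitutive side not needed; evaluate induced variants only
      fit <- env_strategy_fitness(env, variants, k0, wc,
                                  grid = 1, # dummy single-point A grid
                                  weights, integrator)$F_induced
      tibble(k0 = k0, density = d, patchiness = p,
             delta = delta_values, fitness = fit,
             best_delta = delta_values[which.max(fit)])
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  counts <- rows |>
    dplyr::distinct(.data$k0, .data$density, .data$patchiness,
                    .data$best_delta) |>
    dplyr::count(.data$k0, .data$best_delta, name = "n_environments") |>
    tidyr::complete(k0 = k0_values, best_delta = delta_values,
                    fill = list(n_environments = 0L))
  structure(list(per_environment = rows, counts = counts,
                 provenance = list(gamma = gamma, seed = seed,
                                   delta_values = delta_values)),
            class = "delta_scan")
}

#' @export
print.delta_scan <- function(x, ...) {
  cat("<delta_scan>\n")
  print(x$counts)
  invisible(x)
}
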