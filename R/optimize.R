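#' Settings for the stochastic hill climb over the host parameters
#'
#' The induced model's 11 host parameters are optimized by an
#' accept-if-better multiplicative random walk: each proposal multiplies
#' one uniformly chosen free parameter by `exp(u)`, `u ~ U(-step_scale,
#' step_scale)`, and is accepted only if fitness improves. Several
#' independent restarts are run from log-uniform starting draws and the
#' best end point is returned.
#'
#' @param n_iterations proposals per restart.
#' @param n_restarts independent restarts.
#' @param step_scale half-width of the log-scale proposal.
#' @param bounds length-2 positive vector; proposals outside
#'   `[bounds[1], bounds[2]]` are rejected.
#' @param init_range length-2 positive vector; restarts draw starting
#'   values log-uniformly from this range.
#' @param t_end evaluation horizon; `NULL` uses `min(10 * pi / phi, 1000)`
#'   (at least five input periods, capped).
#' @param seed RNG seed.
#' @return An `optimizer_config` list.
#' @export
optimizer_config <- function(n_iterations = 2000, n_restarts = 3,
                             step_scale = 0.5, bounds = c(1e-4, 1e2),
                             init_range = c(0.01, 10), t_end = NULL,
                             seed = NULL) {
  if (n_iterations < 1) abort("n_iterations must be >= 1")
  if (n_restarts < 1) abort("n_restarts must be >= 1")
  if (step_scale <= 0) abort("step_scale must be > 0")
  if (length(bounds) != 2 || bounds[1] <= 0 || bounds[2] <= bounds[1]) {
    abort("bounds must be positive and increasing")
  }
  if (!is.null(t_end) && t_end <= 0) abort("t_end must be > 0")
  structure(list(n_iterations = as.integer(n_iterations),
                 n_restarts = as.integer(n_restarts),
                 step_scale = step_scale, bounds = bounds,
                 init_range = init_range, t_end = t_end, seed = seed),
            class = "optimizer_config")
}

#' Induced-strategy fitness under sinusoidal influx
#'
#' The hill climb's objective: integrate the induced model from the zero
#' state under `f(t) = omega * sin(t * phi)^2` over `[0, t_end]` and return
#' the fitness of the time-averaged components.
#'
#' @param params an [imd_params()].
#' @param phi,omega sinusoidal frequency and amplitude.
#' @param t_end evaluation horizon.
#' @param weights a [fitness_weights()].
#' @param integrator an [integrator_config()]; its `t_end` is replaced.
#' @return Fitness in (0, 1], or `NA` if the integration blows up.
#' @export
sinusoidal_fitness <- function(params, phi, omega = 1, t_end = 1000,
                               weights = fitness_weights(),
                               integrator = integrator_config()) {
  integrator$t_end <- t_end
  res <- induced_means(params, sinusoidal_input(omega, phi), integrator)
  if (res$blown || any(!is.finite(res$means))) return(NA_real_)
  fitness_induced(res$means, weights)
}

default_t_end <- function(phi, cap = 1000) min(10 * pi / phi, cap)

#' Optimize the induced defense by stochastic hill climbing
#'
#' Searches the 11-dimensional host-parameter landscape (lambda2, lambda3,
#' R0, beta1–beta6, Zn, Zs) for the parameter set maximizing induced
#' fitness under a deterministic sinusoidal encounter input with frequency
#' `phi`. Bacterial attributes (`alpha`, `k0`, `lambda1`) stay fixed. A
#' subset of the free dimensions can be selected with `free` (the rest stay
#' at their `base` values), which is how reduced-landscape checks are run.
#'
#' @param phi sinusoidal encounter frequency used for optimization.
#' @param k0 bacterial proliferation rate.
#' @param alpha PG-release rate.
#' @param lambda1 PG degradation rate.
#' @param omega sinusoidal amplitude.
#' @param cfg an [optimizer_config()].
#' @param free names of the parameters to optimize (subset of
#'   [free_param_names()]).
#' @param base an [imd_params()] supplying fixed values (and starting
#'   values when `init` is `"base"`).
#' @param init `"random"` (log-uniform draws per restart) or `"base"`.
#' @param weights a [fitness_weights()].
#' @param integrator an [integrator_config()].
#' @return An `imd_opt` object: optimized `params`, achieved `fitness`,
#'   acceptance `trace` (one row per accepted proposal), and provenance.
#'   Supports [tidy()] and [glance()].
#' @export
optimize_induced <- function(phi, k0 = 0.1, alpha = 2, lambda1 = 0.01,
                             omega = 1, cfg = optimizer_config(),
                             free = free_param_names(),
                             base = NULL, init = c("random", "base"),
                             weights = fitness_weights(),
                             integrator = integrator_config()) {
  init <- match.arg(init)
  stopifnot(inherits(cfg, "optimizer_config"))
  bad <- setdiff(free, free_param_names())
  if (length(bad) > 0) {
    abort(paste0("not optimizable: ", paste(bad, collapse = ", ")))
  }
  if (is.null(base)) base <- imd_params(alpha = alpha, k0 = k0,
                                        lambda1 = lambda1)
  base$alpha <- alpha; base$k0 <- k0; base$lambda1 <- lambda1
  t_end <- if (is.null(cfg$t_end)) default_t_end(phi) else cfg$t_end
  evaluate <- function(p) {
    sinusoidal_fitness(p, phi, omega, t_end, weights, integrator)
  }

  run_restart <- function(r) {
    seed <- if (is.null(cfg$seed)) NULL else
      child_seed(cfg$seed, paste0("restart:", r))
    body <- function() {
      p <- base
      if (init == "random") {
        draws <- exp(runif(length(free), log(cfg$init_range[1]),
                           log(cfg$init_range[2])))
        p[free] <- as.list(draws)
      }
      f_cur <- evaluate(p)
      f_init <- f_cur
      # the trace records finite evaluated fitness only; a random start
      # whose integration blows up enters as -Inf and never appears
      trace <- if (is.na(f_cur)) list() else
        list(list(iteration = 0L, fitness = f_cur,
                  parameter = NA_character_))
      if (is.na(f_cur)) f_cur <- -Inf
      for (it in seq_len(cfg$n_iterations)) {
        pick <- free[sample.int(length(free), 1)]
        u <- runif(1, -cfg$step_scale, cfg$step_scale)
        cand <- p
        cand[[pick]] <- p[[pick]] * exp(u)
        if (cand[[pick]] < cfg$bounds[1] || cand[[pick]] > cfg$bounds[2]) {
          next
        }
        f_new <- evaluate(cand)
        if (!is.na(f_new) && f_new > f_cur) {
          p <- cand
          f_cur <- f_new
          trace[[length(trace) + 1]] <-
            list(iteration = it, fitness = f_cur, parameter = pick)
        }
      }
      tr <- if (length(trace) == 0) {
        tibble(iteration = integer(0), fitness = numeric(0),
               parameter = character(0))
      } else {
        dplyr::bind_rows(trace)
      }
      list(params = p, fitness = f_cur, f_init = f_init, trace = tr)
    }
    res <- if (is.null(seed)) body() else withr::with_seed(seed, body())
    res$trace$restart <- r
    res
  }

  restarts <- purrr::map(seq_len(cfg$n_restarts), run_restart)
  fits <- purrr::map_dbl(restarts, "fitness")
  best <- restarts[[which.max(fits)]]
  structure(list(
    strategy = "induced",
    params = best$params,
    fitness = best$fitness,
    trace = dplyr::bind_rows(purrr::map(restarts, "trace")),
    restart_fitness = fits,
    provenance = list(phi = phi, k0 = k0, alpha = alpha, lambda1 = lambda1,
                      omega = omega, t_end = t_end, free = free,
                      n_iterations = cfg$n_iterations,
                      n_restarts = cfg$n_restarts, seed = cfg$seed,
                      weights = weights$mode)
  ), class = "imd_opt")
}

#' Constitutive fitness as a function of the standing AMP level
#'
#' Scans the AMP grid for one environment (stochastic walks) or one
#' deterministic input and returns the mean per-walk fitness at each grid
#' value — the raw curve whose maximum [optimize_constitutive()] picks and
#' which the multi-environment sampler averages across environments.
#'
#' @param x a `bact_env` or an `imd_input`.
#' @param k0 bacterial proliferation rate.
#' @param grid increasing vector of candidate AMP levels.
#' @param walk_cfg a [walk_config()] (environment input).
#' @param t_end horizon for deterministic inputs.
#' @param weights a [fitness_weights()].
#' @param integrator an [integrator_config()] (deterministic inputs).
#' @return A tibble with columns `A` and `fitness`.
#' @export
constitutive_fitness_curve <- function(x, k0,
                                       grid = seq(0.01, 2, by = 0.01),
                                       walk_cfg = walk_config(),
                                       t_end = 1000,
                                       weights = fitness_weights(),
                                       integrator = integrator_config()) {
  if (length(grid) < 1 || any(diff(grid) <= 0) || any(grid <= 0)) {
    abort("grid must be positive and increasing")
  }
  if (inherits(x, "bact_env")) {
    spec <- attr(x, "spec")
    cm <- env_count_matrix(x)
    fit_mat <- vapply(seq_len(walk_cfg$n_walks), function(w) {
      influx <- walk_influx(cm, spec$size, walk_cfg, w)$influx
      bbar <- const_bbar_grid_cpp(influx, walk_cfg$dt_per_step, k0, grid, 0)
      exp(-(weights$weight_B * bbar + weights$weight_A * grid))
    }, numeric(length(grid)))
    tibble(A = grid, fitness = rowMeans(fit_mat))
  } else if (inherits(x, "imd_input")) {
    method <- match(integrator$method, c("euler", "rk4")) - 1L
    dt_step <- if (is.finite(x$dt_per_step)) x$dt_per_step else t_end
    fit <- vapply(grid, function(A) {
      res <- const_integrate_cpp(0, A, k0, x$mode, x$omega, x$phi, x$influx,
                                 dt_step, integrator$h, t_end,
                                 integrator$record_stride, method,
                                 integrator$clip_negative, TRUE)
      if (res$blown_step >= 0) return(0)
      fitness_constitutive(res$B_mean, A, weights)
    }, numeric(1))
    tibble(A = grid, fitness = fit)
  } else {
    abort("x must be a bact_env or an imd_input")
  }
}

#' Optimize the constitutive defense by grid search
#'
#' Evaluates the constitutive fitness `exp(-(B + A))` for every AMP level
#' on the grid (0.01 to 2 in steps of 0.01 by default) and returns the
#' maximizer; ties break toward the smaller — cheaper — level. Against an
#' environment the fitness at each level is the arithmetic mean of
#' per-walk fitness across stochastic sojourns.
#'
#' @inheritParams constitutive_fitness_curve
#' @return An `imd_opt` object with the optimal `A`, its `fitness` and the
#'   full fitness `curve`. Supports [tidy()] and [glance()].
#' @export
optimize_constitutive <- function(x, k0, grid = seq(0.01, 2, by = 0.01),
                                  walk_cfg = walk_config(), t_end = 1000,
                                  weights = fitness_weights(),
                                  integrator = integrator_config()) {
  curve <- constitutive_fitness_curve(x, k0, grid, walk_cfg, t_end,
                                      weights, integrator)
  best <- which.max(curve$fitness) # first max: smallest A on ties
  structure(list(
    strategy = "constitutive",
    A = curve$A[best],
    fitness = curve$fitness[best],
    curve = curve,
    provenance = list(k0 = k0, grid_range = range(grid),
                      n_grid = length(grid),
                      n_walks = if (inherits(x, "bact_env"))
                        walk_cfg$n_walks else NA_integer_,
                      seed = if (inherits(x, "bact_env"))
                        walk_cfg$seed else NULL,
                      weights = weights$mode)
  ), class = "imd_opt")
}

#' Optimize one constitutive level across several environments
#'
#' A single standing AMP level must serve every environment the fly may
#' inhabit: for each grid value the probability-weighted mean of the
#' per-environment fitness curves is computed and the maximizing level
#' returned (ties toward smaller A).
#'
#' @param envs list of `bact_env` objects, or a list of precomputed curves
#'   from [constitutive_fitness_curve()] (all on the same grid).
#' @param probabilities weights summing to 1 (default equal).
#' @inheritParams optimize_constitutive
#' @return An `imd_opt` as for [optimize_constitutive()].
#' @export
optimize_constitutive_multi <- function(envs, probabilities = NULL, k0 = 0.1,
                                        grid = seq(0.01, 2, by = 0.01),
                                        walk_cfg = walk_config(),
                                        weights = fitness_weights()) {
  n <- length(envs)
  if (n < 1) abort("envs must be non-empty")
  if (is.null(probabilities)) probabilities <- rep(1 / n, n)
  if (length(probabilities) != n) {
    abort("probabilities must match the number of environments")
  }
  if (abs(sum(probabilities) - 1) > 1e-8) {
    abort("probabilities must sum to 1")
  }
  curves <- purrr::map(envs, function(e) {
    if (inherits(e, "bact_env")) {
      constitutive_fitness_curve(e, k0, grid, walk_cfg, weights = weights)
    } else {
      stopifnot(is.data.frame(e), all(c("A", "fitness") %in% names(e)))
      e
    }
  })
  fmat <- do.call(cbind, purrr::map(curves, "fitness"))
  mean_curve <- as.numeric(fmat %*% probabilities)
  best <- which.max(mean_curve)
  structure(list(
    strategy = "constitutive",
    A = curves[[1]]$A[best],
    fitness = mean_curve[best],
    curve = tibble(A = curves[[1]]$A, fitness = mean_curve),
    provenance = list(k0 = k0, n_envs = n, probabilities = probabilities,
                      seed = walk_cfg$seed, weights = weights$mode)
  ), class = "imd_opt")
}

#' @export
print.imd_opt <- function(x, ...) {
  cat(sprintf("<imd_opt: %s strategy, fitness %.6g>\n", x$strategy,
              x$fitness))
  if (x$strategy == "constitutive") {
    cat(sprintf("  optimal A = %.4g (grid of %d)\n", x$A,
                nrow(x$curve)))
  } else {
    cat(sprintf("  %d restarts, %d accepted proposals\n",
                length(x$restart_fitness),
                sum(!is.na(x$trace$parameter))))
  }
  invisible(x)
}

#' Tidy an optimization result
#'
#' @param x an `imd_opt`.
#' @param ... unused.
#' @return One row per parameter: `term`, `estimate`, and for the induced
#'   strategy whether the dimension was free in the search.
#' @method tidy imd_opt
#' @export
tidy.imd_opt <- function(x, ...) {
  if (x$strategy == "constitutive") {
    tibble(term = "A", estimate = x$A)
  } else {
    v <- unlist(x$params)
    tibble(term = names(v), estimate = unname(v),
           free = names(v) %in% x$provenance$free)
  }
}

#' One-row summary of an optimization result
#'
#' @param x an `imd_opt`.
#' @param ... unused.
#' @return A one-row tibble with the strategy, achieved fitness and search
#'   size.
#' @method glance imd_opt
#' @export
glance.imd_opt <- function(x, ...) {
  if (x$strategy == "constitutive") {
    tibble(strategy = x$strategy, fitness = x$fitness,
           n_evaluated = nrow(x$curve), n_accepted = NA_integer_)
  } else {
    tibble(strategy = x$strategy, fitness = x$fitness,
           n_evaluated = x$provenance$n_iterations *
             x$provenance$n_restarts,
           n_accepted = sum(!is.na(x$trace$parameter)))
  }
}
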