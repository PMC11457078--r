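#' Random-walk configuration
#'
#' Settings for a fly's stochastic sojourn through an environment: a simple
#' random walk on the toroidal lattice, one move per step, with bacterial
#' influx `dose * colony count` while the fly occupies a colony cell.
#'
#' @param n_steps steps per walk.
#' @param n_walks number of independent walks.
#' @param dt_per_step simulated time per walk step.
#' @param dose bacterial influx rate contributed by each colony in the
#'   occupied cell.
#' @param neighborhood `"von_neumann"` (4 neighbors) or `"moore"` (8).
#' @param seed RNG seed; each walk derives its own child seed so walk k is
#'   reproducible in isolation.
#' @return A `walk_config` list.
#' @export
walk_config <- function(n_steps = 5000, n_walks = 100, dt_per_step = 1,
                        dose = 1, neighborhood = c("von_neumann", "moore"),
                        seed = NULL) {
  neighborhood <- match.arg(neighborhood)
  n_steps <- as.integer(n_steps)
  n_walks <- as.integer(n_walks)
  if (is.na(n_steps) || n_steps < 1) abort("n_steps must be >= 1")
  if (is.na(n_walks) || n_walks < 1) abort("n_walks must be >= 1")
  if (!is.finite(dt_per_step) || dt_per_step <= 0) {
    abort("dt_per_step must be > 0")
  }
  if (!is.finite(dose) || dose < 0) abort("dose must be >= 0")
  structure(list(n_steps = n_steps, n_walks = n_walks,
                 dt_per_step = dt_per_step, dose = dose,
                 neighborhood = neighborhood, seed = seed),
            class = "walk_config")
}

#' Sinusoidal influx value
#'
#' Evaluates the deterministic oscillating encounter model
#' `f(t) = omega * sin(t * phi)^2`.
#'
#' @param input a [sinusoidal_input()].
#' @param t time (>= 0), vectorized.
#' @return Non-negative influx value(s).
#' @examples
#' sinusoidal_f(sinusoidal_input(omega = 2, phi = 0.1), t = pi / 0.2)
#' @export
sinusoidal_f <- function(input, t) {
  stopifnot(inherits(input, "imd_input"), input$mode == 0L)
  if (any(t < 0)) abort("t must be >= 0")
  input$omega * sin(t * input$phi)^2
}

# lean internal: positions and influx of one walk, as plain vectors
walk_influx <- function(count_mat, size, cfg, walk_index, keep_path = FALSE) {
  seed <- if (is.null(cfg$seed)) NULL else
    child_seed(cfg$seed, paste0("walk:", walk_index))
  roll <- function() {
    moves <- switch(cfg$neighborhood,
      von_neumann = cbind(c(-1L, 1L, 0L, 0L), c(0L, 0L, -1L, 1L)),
      moore = cbind(rep(c(-1L, 0L, 1L), 3), rep(c(-1L, 0L, 1L), each = 3))
    )
    if (cfg$neighborhood == "moore") moves <- moves[-5, , drop = FALSE]
    start <- c(sample.int(size, 1), sample.int(size, 1))
    dir <- sample.int(nrow(moves), cfg$n_steps, replace = TRUE)
    rows <- (start[1] - 1L + cumsum(moves[dir, 1])) %% size + 1L
    cols <- (start[2] - 1L + cumsum(moves[dir, 2])) %% size + 1L
    # influx on step interval k comes from the cell occupied during it:
    # the position after move k-1 (the start cell for k = 1)
    occ_r <- c(start[1], rows[-cfg$n_steps])
    occ_c <- c(start[2], cols[-cfg$n_steps])
    influx <- cfg$dose * count_mat[cbind(occ_r, occ_c)]
    list(influx = influx, rows = occ_r, cols = occ_c)
  }
  w <- if (is.null(seed)) roll() else withr::with_seed(seed, roll())
  if (!keep_path) w$rows <- w$cols <- NULL
  w
}

#' Simulate one random walk through an environment
#'
#' The fly starts on a uniformly random cell and moves to a uniformly
#' random neighboring cell each step (toroidal boundary). While it occupies
#' a cell holding colonies it ingests bacteria at rate
#' `dose * colony count`; elsewhere influx is zero. Deterministic given
#' `(cfg$seed, walk_index)`.
#'
#' @param env a `bact_env` from [generate_environment()].
#' @param cfg a [walk_config()].
#' @param walk_index which walk (1-based, `<= cfg$n_walks`).
#' @return A tibble of class `encounter_series` with columns `step`,
#'   `time` (interval start), `row`, `col`, `influx`.
#' @export
simulate_walk <- function(env, cfg, walk_index = 1) {
  stopifnot(inherits(env, "bact_env"), inherits(cfg, "walk_config"))
  if (walk_index < 1 || walk_index > cfg$n_walks) {
    abort("walk_index must be in [1, n_walks]")
  }
  spec <- attr(env, "spec")
  w <- walk_influx(env_count_matrix(env), spec$size, cfg, walk_index,
                   keep_path = TRUE)
  out <- tibble(step = seq_len(cfg$n_steps),
                time = (seq_len(cfg$n_steps) - 1) * cfg$dt_per_step,
                row = w$rows, col = w$cols, influx = w$influx)
  attr(out, "dt_per_step") <- cfg$dt_per_step
  class(out) <- c("encounter_series", class(out))
  out
}

#' Run a strategy through stochastic sojourns of an environment
#'
#' For each of `cfg$n_walks` random walks, integrates the chosen model
#' under the walk's piecewise-constant influx over total time
#' `n_steps * dt_per_step` and reports the time-averaged value of every
#' state variable — the raw material of the fitness functions. The induced
#' model is integrated with the fixed-step kernel; the constitutive model
#' uses the exact per-interval solution of its linear equation.
#'
#' @param env a `bact_env`.
#' @param cfg a [walk_config()].
#' @param model `"induced"` or `"constitutive"`.
#' @param params an [imd_params()] (induced model; also supplies `k0` for
#'   the constitutive model unless `k0` is given).
#' @param A_const constant AMP level (constitutive model).
#' @param k0 bacterial proliferation rate override (constitutive model).
#' @param integrator an [integrator_config()]; `t_end` is ignored (set by
#'   the walk length) and `h` must divide `dt_per_step` evenly.
#' @return A tibble with one row per walk: `walk`, `f_mean`, the
#'   time-averaged components (`B` ... `A` for induced, `B` and `A` for
#'   constitutive) and `clip_count`.
#' @export
run_encounter_simulation <- function(env, cfg,
                                     model = c("induced", "constitutive"),
                                     params = imd_params(), A_const = NULL,
                                     k0 = NULL,
                                     integrator = integrator_config()) {
  model <- match.arg(model)
  stopifnot(inherits(env, "bact_env"), inherits(cfg, "walk_config"))
  n_sub <- cfg$dt_per_step / integrator$h
  if (abs(n_sub - round(n_sub)) > 1e-8) {
    abort("integrator h must divide dt_per_step evenly")
  }
  spec <- attr(env, "spec")
  cm <- env_count_matrix(env)
  t_total <- cfg$n_steps * cfg$dt_per_step
  cfg_i <- integrator
  cfg_i$t_end <- t_total

  rows <- purrr::map(seq_len(cfg$n_walks), function(w) {
    influx <- walk_influx(cm, spec$size, cfg, w)$influx
    if (model == "induced") {
      validate_imd_params(params)
      res <- induced_means(params, piecewise_input(influx, cfg$dt_per_step),
                           cfg_i)
      if (res$blown) {
        abort(sprintf("integration blew up in walk %d", w))
      }
      c(walk = w, f_mean = res$f_mean, res$means,
        clip_count = res$clip_count)
    } else {
      if (is.null(A_const)) abort("constitutive model needs A_const")
      k0v <- if (is.null(k0)) params$k0 else k0
      bbar <- const_bbar_grid_cpp(influx, cfg$dt_per_step, k0v, A_const, 0)
      c(walk = w, f_mean = mean(influx), B = bbar, A = A_const,
        clip_count = 0)
    }
  })
  dplyr::bind_rows(purrr::map(rows, ~ as_tibble(as.list(.x))))
}
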