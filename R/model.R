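#' Right-hand side of the nine-equation induced Imd model
#'
#' Evaluates the instantaneous rates of change of the nine pathway species:
#' bacteria B proliferate at rate `k0` and are killed by AMP (A); free
#' peptidoglycan G is shed in proportion to bacterial proliferation
#' (`alpha * k0 * B`), scavenged by PGRP-LB (L), bound by receptors (R) into
#' the complex C, recycled when Pirk (P) pulls the complex down or when it
#' dissociates (`lambda3`), and degraded at `lambda1`; active Relish N is
#' produced from the complex at `beta2`; Relish drives receptor induction
#' and the three negative regulators L, P, S through saturating occupancy
#' terms `N / (N + Zn)`; AMP transcription is Relish-driven but repressed by
#' the repressosome S through the competitive occupancy
#' `N / (N + Zn + Zn * S / Zs)`. All of R, N, L, P, S, A share degradation
#' rate `lambda2`.
#'
#' @param state named numeric vector of the nine non-negative concentrations
#'   (B, G, R, C, N, L, P, S, A), e.g. from [zero_state()].
#' @param params an [imd_params()] object.
#' @param f_t non-negative bacterial influx at this instant.
#' @return Named numeric vector of the nine time derivatives.
#' @examples
#' induced_derivatives(zero_state(), imd_params(), f_t = 0)
#' @export
induced_derivatives <- function(state, params, f_t) {
  state <- check_state(state)
  validate_imd_params(params)
  if (!is.finite(f_t) || f_t < 0) abort("f_t must be finite and >= 0")
  B <- state[["B"]]; G <- state[["G"]]; R <- state[["R"]]
  C <- state[["C"]]; N <- state[["N"]]; L <- state[["L"]]
  P <- state[["P"]]; S <- state[["S"]]; A <- state[["A"]]
  hill <- N / (N + params$Zn)
  c(
    B = f_t + params$k0 * B - A * B,
    G = params$alpha * params$k0 * B - L * G - R * G + P * C +
      params$lambda3 * C - params$lambda1 * G,
    R = params$R0 + params$beta1 * hill - P * R - R * G +
      params$lambda3 * C - params$lambda2 * R,
    C = R * G - P * C - params$lambda3 * C,
    N = params$beta2 * C - params$lambda2 * N,
    L = params$beta3 * hill - params$lambda2 * L,
    P = params$beta4 * hill - params$lambda2 * P,
    S = params$beta5 * hill - params$lambda2 * S,
    A = params$beta6 * N / (N + params$Zn + params$Zn * S / params$Zs) -
      params$lambda2 * A
  )
}

#' Right-hand side of the constitutive-defense model
#'
#' The constitutive strategy keeps the AMP level fixed at `A_const`, so only
#' the bacterial equation remains: influx plus proliferation minus killing.
#'
#' @param B non-negative bacterial density.
#' @param A_const non-negative constant AMP level.
#' @param k0 bacterial proliferation rate.
#' @param f_t non-negative bacterial influx.
#' @return dB/dt, a scalar.
#' @examples
#' constitutive_derivative(B = 1, A_const = 0.5, k0 = 0.1, f_t = 0)
#' @export
constitutive_derivative <- function(B, A_const, k0, f_t) {
  vals <- c(B = B, A_const = A_const, k0 = k0, f_t = f_t)
  if (any(!is.finite(vals)) || any(vals[c("B", "A_const", "f_t")] < 0)) {
    abort("B, A_const and f_t must be finite and >= 0")
  }
  f_t + k0 * B - A_const * B
}

check_state <- function(state) {
  if (is.null(names(state))) names(state) <- state_names()
  state <- state[state_names()]
  if (any(is.na(state))) abort("state must name all of B,G,R,C,N,L,P,S,A")
  if (any(state < 0)) abort("state components must be >= 0")
  state
}

#' Fixed-step integrator settings
#'
#' @param h integration step (time units).
#' @param method `"euler"` or `"rk4"`.
#' @param t_end final time.
#' @param record_stride number of steps between recorded points (1 records
#'   every step). The initial and final states are always recorded.
#' @param clip_negative floor every component at 0 after each step
#'   (concentrations are physical; fixed steps can undershoot). The number
#'   of clipped components is reported on the trajectory.
#' @return An `integrator_config` list.
#' @export
integrator_config <- function(h = 0.01, method = c("euler", "rk4"),
                              t_end = 100, record_stride = 1L,
                              clip_negative = TRUE) {
  method <- match.arg(method)
  if (!is.finite(h) || h <= 0) abort("h must be > 0")
  if (!is.finite(t_end) || t_end < 0) abort("t_end must be >= 0")
  record_stride <- as.integer(record_stride)
  if (is.na(record_stride) || record_stride < 1) {
    abort("record_stride must be >= 1")
  }
  structure(list(h = h, method = method, t_end = t_end,
                 record_stride = record_stride,
                 clip_negative = isTRUE(clip_negative)),
            class = "integrator_config")
}

## --- input constructors -----------------------------------------------

#' Bacterial influx functions f(t)
#'
#' Three influx modes drive the models: a deterministic oscillation
#' `f(t) = omega * sin(t * phi)^2` (`sinusoidal_input()`), a
#' piecewise-constant series as produced by a random walk through an
#' environment (`piecewise_input()`), and a constant level
#' (`constant_input()`).
#'
#' @param omega encounter amplitude (bacteria per unit time).
#' @param phi encounter frequency (per unit time).
#' @param influx non-negative numeric vector, one value per step interval.
#' @param dt_per_step duration of each interval.
#' @param value constant influx level.
#' @return An `imd_input` object consumed by [integrate_model()].
#' @examples
#' integrate_model("constitutive", A_const = 0.5, input = constant_input(0.3),
#'                 config = integrator_config(t_end = 10))
#' @name imd_input
NULL

#' @rdname imd_input
#' @export
sinusoidal_input <- function(omega = 1, phi = 0.01) {
  if (omega < 0 || phi <= 0) abort("need omega >= 0 and phi > 0")
  structure(list(mode = 0L, omega = omega, phi = phi,
                 influx = numeric(0), dt_per_step = 1),
            class = "imd_input")
}

#' @rdname imd_input
#' @export
piecewise_input <- function(influx, dt_per_step = 1) {
  influx <- as.numeric(influx)
  if (length(influx) < 1 || any(!is.finite(influx)) || any(influx < 0)) {
    abort("influx must be non-negative and finite")
  }
  if (dt_per_step <= 0) abort("dt_per_step must be > 0")
  structure(list(mode = 1L, omega = 0, phi = 1, influx = influx,
                 dt_per_step = dt_per_step),
            class = "imd_input")
}

#' @rdname imd_input
#' @export
constant_input <- function(value) {
  piecewise_input(influx = value, dt_per_step = Inf)
}

#' Evaluate an influx object at given times
#'
#' @param input an `imd_input` object.
#' @param t numeric vector of times (>= 0).
#' @return Numeric vector of f(t) values.
#' @examples
#' input_f(sinusoidal_input(omega = 2, phi = 0.1), c(0, pi / 0.2))
#' @export
input_f <- function(input, t) {
  stopifnot(inherits(input, "imd_input"), all(t >= 0))
  if (input$mode == 0L) {
    input$omega * sin(t * input$phi)^2
  } else {
    k <- pmin(floor(t / input$dt_per_step), length(input$influx) - 1)
    input$influx[k + 1]
  }
}

## --- integration -------------------------------------------------------

#' Integrate the induced or constitutive model
#'
#' Fixed-step integration (Euler by default, classical RK4 available) of
#' either the nine-equation induced model or the one-equation constitutive
#' model under a given influx function. A fixed step is used for both
#' because the random-walk influx is piecewise constant with jumps at step
#' boundaries; the default `h = 0.01` matches the grid-search convention
#' used for the constitutive optimum.
#'
#' @param model `"induced"` or `"constitutive"`.
#' @param params an [imd_params()] object (induced model). For the
#'   constitutive model supply `A_const` and `k0` instead.
#' @param input an `imd_input` from [sinusoidal_input()],
#'   [piecewise_input()] or [constant_input()].
#' @param init initial state: named length-9 vector for the induced model
#'   (default [zero_state()]), scalar B(0) for the constitutive model
#'   (default 0).
#' @param config an [integrator_config()].
#' @param A_const constant AMP level (constitutive model only).
#' @param k0 bacterial proliferation rate (constitutive model only).
#' @return A tibble of class `imd_trajectory` with columns `time`, `f` and
#'   the state variables (`B` ... `A`, or just `B`), carrying the clip
#'   counter and settings as attributes.
#' @examples
#' tr <- integrate_model("induced", imd_params(),
#'                       input = sinusoidal_input(1, 0.05),
#'                       config = integrator_config(t_end = 50,
#'                                                  record_stride = 100))
#' tail(tr, 3)
#' @export
integrate_model <- function(model = c("induced", "constitutive"),
                            params = imd_params(), input,
                            init = NULL, config = integrator_config(),
                            A_const = NULL, k0 = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(input, "imd_input"),
            inherits(config, "integrator_config"))
  method <- match(config$method, c("euler", "rk4")) - 1L
  dt_step <- if (is.finite(input$dt_per_step)) input$dt_per_step else
    max(config$t_end, config$h)

  if (model == "induced") {
    validate_imd_params(params)
    if (is.null(init)) init <- zero_state()
    init <- check_state(init)
    res <- imd_integrate_cpp(unname(init), param_vector(params),
                             input$mode, input$omega, input$phi,
                             input$influx, dt_step, config$h, config$t_end,
                             config$record_stride, method,
                             config$clip_negative, FALSE)
    check_blowup(res, state_names())
    states <- res$states
    colnames(states) <- state_names()
    out <- dplyr::bind_cols(tibble(time = res$times, f = res$f),
                            as_tibble(states))
  } else {
    if (is.null(A_const) || is.null(k0)) {
      abort("constitutive model needs A_const and k0")
    }
    if (A_const < 0 || k0 <= 0) abort("need A_const >= 0 and k0 > 0")
    if (is.null(init)) init <- 0
    if (init < 0) abort("init must be >= 0")
    res <- const_integrate_cpp(init, A_const, k0, input$mode, input$omega,
                               input$phi, input$influx, dt_step, config$h,
                               config$t_end, config$record_stride, method,
                               config$clip_negative, FALSE)
    check_blowup(res, "B")
    out <- tibble(time = res$times, f = res$f, B = res$B)
  }
  attr(out, "model") <- model
  attr(out, "clip_count") <- res$clip_count
  attr(out, "config") <- config
  class(out) <- c("imd_trajectory", class(out))
  out
}

check_blowup <- function(res, comps) {
  if (res$blown_step >= 0) {
    abort(sprintf(
      "integration blew up (non-finite value) at step %d in component %s",
      res$blown_step, comps[res$blown_component]))
  }
  invisible(res)
}

# lean path used by the simulation drivers: time-averaged components only
induced_means <- function(params, input, config, init = zero_state()) {
  method <- match(config$method, c("euler", "rk4")) - 1L
  dt_step <- if (is.finite(input$dt_per_step)) input$dt_per_step else
    max(config$t_end, config$h)
  res <- imd_integrate_cpp(unname(check_state(init)), param_vector(params),
                           input$mode, input$omega, input$phi, input$influx,
                           dt_step, config$h, config$t_end,
                           config$record_stride, method,
                           config$clip_negative, TRUE)
  if (res$blown_step >= 0) {
    return(list(means = setNames(rep(NA_real_, 9), state_names()),
                f_mean = NA_real_, clip_count = res$clip_count,
                blown = TRUE))
  }
  list(means = setNames(res$means, state_names()), f_mean = res$f_mean,
       clip_count = res$clip_count, blown = FALSE)
}
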