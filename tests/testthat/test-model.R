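test_that("a silent pathway produces only basal receptors", {
  d <- induced_derivatives(zero_state(), imd_params(), f_t = 0)
  expect_equal(d[["R"]], imd_params()$R0)
  expect_equal(unname(d[setdiff(names(d), "R")]), rep(0, 8))
})

test_that("derivatives match direct substitution", {
  p <- imd_params(k0 = 0.1, alpha = 2, lambda1 = 0.01)
  st <- zero_state(); st["B"] <- 1
  d <- induced_derivatives(st, p, f_t = 0)
  expect_equal(d[["B"]], 0.1)          # k0 * B, no AMP yet
  expect_equal(d[["G"]], 0.2)          # alpha * k0 * B with G = 0
  expect_equal(d[["R"]], p$R0)
  expect_equal(d[["N"]], 0)

  # abundant Relish without repressosome: AMP production saturates at beta6
  st2 <- zero_state(); st2["N"] <- 1e12; st2["A"] <- 0.3
  d2 <- induced_derivatives(st2, p, f_t = 0)
  expect_equal(d2[["A"]], p$beta6 - p$lambda2 * 0.3, tolerance = 1e-9)
})

test_that("derivative preconditions are enforced", {
  expect_error(induced_derivatives(zero_state(), imd_params(), f_t = -1),
               "f_t")
  st <- zero_state(); st["B"] <- -0.1
  expect_error(induced_derivatives(st, imd_params(), f_t = 0), ">= 0")
})

test_that("constitutive derivative arithmetic", {
  expect_equal(constitutive_derivative(1, 0.5, 0.1, 0), -0.4)
  expect_equal(constitutive_derivative(0, 3, 7, 0), 0)
  expect_equal(constitutive_derivative(2, 0.1, 0.1, 0.3), 0.3)
  expect_error(constitutive_derivative(-1, 0.5, 0.1, 0), ">= 0")
  expect_error(constitutive_derivative(1, 0.5, 0.1, -2), ">= 0")
})

test_that("Euler solution tracks the exponential closed form", {
  tr <- integrate_model("constitutive", input = constant_input(0), init = 1,
                        config = integrator_config(h = 0.01, t_end = 10),
                        A_const = 0.5, k0 = 0.1)
  expect_equal(tail(tr$B, 1), exp((0.1 - 0.5) * 10), tolerance = 0.01)
})

test_that("a zero-length integration returns only the initial state", {
  tr <- integrate_model("constitutive", input = constant_input(1), init = 2,
                        config = integrator_config(t_end = 0),
                        A_const = 0.5, k0 = 0.1)
  expect_equal(nrow(tr), 1)
  expect_equal(tr$B, 2)
  tr2 <- integrate_model("induced", imd_params(),
                         input = sinusoidal_input(1, 0.01),
                         config = integrator_config(t_end = 0))
  expect_equal(nrow(tr2), 1)
  expect_equal(unname(unlist(tr2[1, c("B", "A")])), c(0, 0))
})

test_that("receptor pool relaxes to R0/lambda2 under zero input", {
  p <- imd_params()
  tr <- integrate_model("induced", p, input = constant_input(0),
                        config = integrator_config(t_end = 80,
                                                   record_stride = 100))
  expected <- p$R0 / p$lambda2 * (1 - exp(-p$lambda2 * tr$time))
  expect_equal(tr$R, expected, tolerance = 0.01)
  # nothing else moves without bacteria
  others <- setdiff(c("B", "G", "C", "N", "L", "P", "S", "A"), "R")
  expect_true(all(as.matrix(tr[, others]) == 0))
})

test_that("the zero-input steady state is stationary", {
  p <- imd_params()
  init <- zero_state(); init["R"] <- p$R0 / p$lambda2
  tr <- integrate_model("induced", p, input = constant_input(0),
                        init = init,
                        config = integrator_config(t_end = 20))
  expect_lt(max(abs(tr$R - p$R0 / p$lambda2)), 1e-8)
})

test_that("clipped trajectories stay non-negative for random parameters", {
  withr::with_seed(42, {
    for (i in 1:12) {
      draws <- exp(rnorm(11, 0, 1.5))
      p <- do.call(imd_params, as.list(setNames(draws, free_param_names())))
      tr <- integrate_model("induced", p,
                            input = sinusoidal_input(runif(1, 0, 3),
                                                     runif(1, 0.01, 0.5)),
                            config = integrator_config(t_end = 20,
                                                       record_stride = 20))
      expect_true(all(as.matrix(tr[, c("B", "G", "R", "C", "N", "L", "P",
                                       "S", "A")]) >= 0))
    }
  })
})

test_that("the derivative field has the expected monotonicities", {
  p <- imd_params()
  base <- zero_state()
  base[c("B", "G", "R", "C", "N", "L", "P", "S", "A")] <-
    c(1, 0.5, 0.8, 0.4, 2, 0.3, 0.6, 1.5, 0.7)

  # stronger repressosome presence slows AMP production
  more_S <- base; more_S["S"] <- base[["S"]] + 1
  expect_lt(induced_derivatives(more_S, p, 0)[["A"]],
            induced_derivatives(base, p, 0)[["A"]])
  # weaker binding (larger Zs) relieves repression
  p_weak <- p; p_weak$Zs <- p$Zs * 10
  expect_gt(induced_derivatives(base, p_weak, 0)[["A"]],
            induced_derivatives(base, p, 0)[["A"]])
  # Pirk removes receptors and complexes
  more_P <- base; more_P["P"] <- base[["P"]] + 1
  expect_lt(induced_derivatives(more_P, p, 0)[["C"]],
            induced_derivatives(base, p, 0)[["C"]])
  expect_lt(induced_derivatives(more_P, p, 0)[["R"]],
            induced_derivatives(base, p, 0)[["R"]])
  # PGRP-LB scavenges free peptidoglycan
  more_L <- base; more_L["L"] <- base[["L"]] + 1
  expect_lt(induced_derivatives(more_L, p, 0)[["G"]],
            induced_derivatives(base, p, 0)[["G"]])
})

test_that("bacterial load keeps growing without AMP defense", {
  p <- imd_params(beta6 = 0)
  bbar <- vapply(c(25, 50, 100), function(T) {
    tr <- integrate_model("induced", p, input = constant_input(0.5),
                          config = integrator_config(t_end = T,
                                                     record_stride = 10))
    mean(tr$B)
  }, numeric(1))
  expect_true(all(diff(bbar) > 0))
})

test_that("integration blow-up names the failing component", {
  expect_error(
    integrate_model("constitutive", input = constant_input(1), init = 1,
                    config = integrator_config(t_end = 100),
                    A_const = 0, k0 = 10),
    "blew up.*component B")
})

test_that("the fixed-step solution matches an adaptive reference solver", {
  p <- imd_params()
  ours <- integrate_model("induced", p, input = sinusoidal_input(1, 0.01),
                          config = integrator_config(h = 0.005,
                                                     method = "rk4",
                                                     t_end = 100,
                                                     record_stride = 200))
  rhs <- function(t, y, parms) {
    list(unname(induced_derivatives(setNames(y, names(zero_state())),
                                    p, sin(0.01 * t)^2)))
  }
  ref <- deSolve::lsoda(unname(zero_state()), times = seq(0, 100, 1),
                        func = rhs, rtol = 1e-8, atol = 1e-10)
  for (i in c(1, 5, 9)) { # B, N, A
    expect_equal(ours[[names(zero_state())[i]]], unname(ref[, i + 1]),
                 tolerance = 1e-4)
  }
})

test_that("one Euler step of the kernel equals the R derivative field", {
  p <- imd_params()
  st <- zero_state()
  st[c("B", "G", "N", "S", "A")] <- c(1, 0.4, 2, 1.5, 0.7)
  h <- 0.01
  tr <- integrate_model("induced", p, input = constant_input(0.3),
                        init = st, config = integrator_config(h = h,
                                                              t_end = h))
  manual <- st + h * induced_derivatives(st, p, 0.3)
  expect_equal(unname(unlist(tr[2, names(st)])), unname(manual),
               tolerance = 1e-12)
})
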