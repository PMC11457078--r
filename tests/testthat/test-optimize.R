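quick_cfg <- function(seed, iters = 60, restarts = 2) {
  optimizer_config(n_iterations = iters, n_restarts = restarts,
                   t_end = 200, seed = seed)
}

test_that("the hill climb only ever accepts improvements", {
  opt <- optimize_induced(phi = 0.05, cfg = quick_cfg(31))
  for (r in unique(opt$trace$restart)) {
    seq_r <- opt$trace$fitness[opt$trace$restart == r]
    expect_true(all(diff(seq_r) > 0))
    expect_gte(opt$fitness, seq_r[1])
  }
  expect_equal(opt$fitness, max(opt$restart_fitness))
})

test_that("optimization is reproducible from its seed", {
  a <- optimize_induced(phi = 0.05, cfg = quick_cfg(32))
  b <- optimize_induced(phi = 0.05, cfg = quick_cfg(32))
  expect_identical(a$params, b$params)
  expect_identical(a$fitness, b$fitness)
})

test_that("without bacteria the optimizer reports perfect fitness", {
  opt <- optimize_induced(phi = 0.05, omega = 0, cfg = quick_cfg(33, 10, 1))
  expect_equal(opt$fitness, 1)
})

test_that("a reduced search space leaves fixed parameters untouched", {
  base <- imd_params()
  opt <- optimize_induced(phi = 0.05, free = c("beta6", "lambda2"),
                          base = base, cfg = quick_cfg(34, 40, 1))
  fixed <- setdiff(free_param_names(), c("beta6", "lambda2"))
  expect_identical(opt$params[fixed], base[fixed])
})

test_that("a threat-free environment pushes constitutive AMP to the floor", {
  opt <- optimize_constitutive(zero_env(), k0 = 0.1,
                               walk_cfg = walk_config(n_steps = 200,
                                                      n_walks = 2,
                                                      seed = 3))
  expect_equal(opt$A, 0.01)
  expect_equal(opt$fitness, exp(-0.01))
})

test_that("heavy constant influx forces A above the proliferation rate", {
  opt <- optimize_constitutive(constant_input(2), k0 = 0.1, t_end = 300)
  expect_gt(opt$A, 0.1)
})

test_that("a one-point grid is returned as-is", {
  opt <- optimize_constitutive(constant_input(0.3), k0 = 0.1,
                               grid = 0.4, t_end = 100)
  expect_equal(opt$A, 0.4)
})

test_that("the grid search agrees with an independent per-point re-scan", {
  env <- generate_environment(environment_spec(
    size = 30, density = 40, patchiness = 2, seed = 5))
  wc <- walk_config(n_steps = 300, n_walks = 5, seed = 7)
  grid <- seq(0.05, 1, by = 0.05)
  opt <- optimize_constitutive(env, k0 = 0.1, grid = grid, walk_cfg = wc)
  # independent route: one run_encounter_simulation per A, shuffled order
  shuffled <- withr::with_seed(1, sample(grid))
  rescanned <- vapply(shuffled, function(A) {
    s <- run_encounter_simulation(env, wc, model = "constitutive",
                                  A_const = A, k0 = 0.1)
    mean(vapply(seq_len(nrow(s)),
                function(i) fitness_constitutive(s$B[i], A), numeric(1)))
  }, numeric(1))
  best_rescan <- shuffled[which.max(rescanned)]
  expect_equal(opt$A, best_rescan)
  expect_equal(opt$fitness, unname(max(rescanned)), tolerance = 1e-10)
})

test_that("multi-environment optimization handles degenerate mixtures", {
  env <- generate_environment(environment_spec(
    size = 30, density = 60, patchiness = 3, seed = 9))
  wc <- walk_config(n_steps = 300, n_walks = 5, seed = 11)
  grid <- seq(0.01, 1, by = 0.01)
  single <- optimize_constitutive(env, k0 = 0.1, grid = grid, walk_cfg = wc)
  same3 <- optimize_constitutive_multi(list(env, env, env), k0 = 0.1,
                                       grid = grid, walk_cfg = wc)
  expect_equal(same3$A, single$A)
  other <- generate_environment(environment_spec(
    size = 30, density = 5, patchiness = 1, seed = 10))
  pinned <- optimize_constitutive_multi(list(env, other),
                                        probabilities = c(1, 0), k0 = 0.1,
                                        grid = grid, walk_cfg = wc)
  expect_equal(pinned$A, single$A)
  expect_error(optimize_constitutive_multi(list(env, other),
                                           probabilities = c(0.4, 0.4),
                                           k0 = 0.1, walk_cfg = wc),
               "sum to 1")
})

test_that("a two-environment mixture optimum lies between the marginals", {
  # synthetic unimodal curves with well-separated argmaxes
  grid <- seq(0.01, 2, by = 0.01)
  c1 <- tibble::tibble(A = grid, fitness = exp(-(grid - 0.3)^2 / 0.02))
  c2 <- tibble::tibble(A = grid, fitness = exp(-(grid - 1.4)^2 / 0.02))
  mixed <- optimize_constitutive_multi(list(c1, c2),
                                       probabilities = c(0.5, 0.5),
                                       grid = grid)
  # exhaustive oracle on the averaged curve
  oracle_A <- grid[which.max((c1$fitness + c2$fitness) / 2)]
  expect_equal(mixed$A, oracle_A)
  expect_gte(mixed$A, 0.3)
  expect_lte(mixed$A, 1.4)
})

test_that("optimizer results tidy and glance cleanly", {
  opt <- optimize_induced(phi = 0.05, cfg = quick_cfg(35, 20, 1))
  td <- tidy(opt)
  expect_setequal(td$term, names(imd_params()))
  expect_equal(sum(td$free), 11)
  g <- glance(opt)
  expect_equal(g$strategy, "induced")
  expect_equal(g$n_evaluated, 20)
  co <- optimize_constitutive(constant_input(0.2), k0 = 0.1, grid = c(0.1, 0.2),
                              t_end = 50)
  expect_equal(tidy(co)$term, "A")
  expect_equal(glance(co)$n_evaluated, 2)
})
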