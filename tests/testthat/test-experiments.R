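small_walks <- function(n_steps = 400, n_walks = 8) {
  walk_config(n_steps = n_steps, n_walks = n_walks)
}

test_that("a colony-free cell favors induction at the AMP floor", {
  g <- run_fitness_grid(imd_params(), k0 = 0.1, densities = c(0, 20),
                        patchiness_levels = 1, size = 30,
                        walk_cfg = small_walks(), seed = 3)
  zero_row <- g[g$density == 0, ]
  expect_equal(zero_row$F_induced, 1)
  expect_equal(zero_row$F_constitutive, exp(-0.01))
  expect_equal(zero_row$A_opt, 0.01)
  expect_lt(zero_row$delta_F, 0)
})

test_that("fitness grids have consistent shape and are reproducible", {
  g <- run_fitness_grid(imd_params(), k0 = 0.1, densities = 10,
                        patchiness_levels = 1, size = 30,
                        walk_cfg = small_walks(), seed = 5)
  expect_equal(nrow(g), 1)
  expect_equal(g$delta_F, g$F_constitutive - g$F_induced)
  g2 <- run_fitness_grid(imd_params(), k0 = 0.1, densities = 10,
                         patchiness_levels = 1, size = 30,
                         walk_cfg = small_walks(), seed = 5)
  expect_equal(as.data.frame(g), as.data.frame(g2))
})

test_that("PIW counts strict induced wins over cells", {
  expect_equal(compute_piw(rep(TRUE, 4)), 1)
  # exact ties count as constitutive wins
  tied <- tibble::tibble(F_induced = c(0.5, 0.5),
                         F_constitutive = c(0.5, 0.5))
  expect_equal(compute_piw(tied), 0)
  mixed <- tibble::tibble(F_induced = c(0.9, 0.9, 0.9, rep(0.1, 5)),
                          F_constitutive = c(rep(0.5, 8)))
  expect_equal(compute_piw(mixed), 0.375)
  shuffled <- mixed[withr::with_seed(2, sample(nrow(mixed))), ]
  expect_equal(compute_piw(shuffled), 0.375)
  expect_error(compute_piw(logical(0)), "non-empty")
  expect_true(compute_piw(c(TRUE, FALSE)) >= 0 &&
                compute_piw(c(TRUE, FALSE)) <= 1)
})

test_that("single-environment draws from a constitutive-favored pool lose", {
  grid <- seq(0.01, 1, by = 0.01)
  # constitutive beats induction in every pool member by construction
  curves <- cbind(exp(-(grid - 0.2)^2) * 0.9, exp(-(grid - 0.8)^2) * 0.9)
  pool <- make_pool(F_induced = c(0.6, 0.6), curves = curves, grid = grid)
  expect_equal(sample_multi_environment(pool, j = 1, n_repeats = 200,
                                        seed = 1)$piw, 0)
})

test_that("a two-environment pool reproduces the exhaustive oracle", {
  grid <- seq(0.01, 2, by = 0.01)
  # far-apart constitutive optima: one standing level cannot serve both
  c1 <- exp(-(grid - 0.1)^2 / 0.005) * 0.92
  c2 <- exp(-(grid - 1.8)^2 / 0.005) * 0.92
  pool <- make_pool(F_induced = c(0.9, 0.9), curves = cbind(c1, c2),
                    grid = grid)
  # oracle: with j = 2 the draw is the whole pool, a single outcome
  f_ind <- mean(pool$F_induced)
  f_con <- max((c1 + c2) / 2)
  expect_true(f_ind > f_con) # heterogeneity penalizes the single A
  res <- sample_multi_environment(pool, j = 2, n_repeats = 50, seed = 2)
  expect_equal(res$piw, 1)
  # j = 1 must lose everywhere (each member favors constitutive)
  expect_equal(sample_multi_environment(pool, j = 1, n_repeats = 200,
                                        seed = 3)$piw, 0)
})

test_that("two-environment weights reduce to single draws at the endpoints", {
  grid <- seq(0.01, 2, by = 0.01)
  c1 <- exp(-(grid - 0.1)^2 / 0.005) * 0.92
  c2 <- exp(-(grid - 1.8)^2 / 0.005) * 0.92
  pool <- make_pool(F_induced = c(0.9, 0.9), curves = cbind(c1, c2),
                    grid = grid)
  for (q in c(0, 1)) {
    res <- sample_multi_environment(pool, q = q, n_repeats = 300, seed = 4)
    expect_equal(res$piw, 0) # endpoint = single environment = pool loses
  }
  # symmetry of the weighted comparison: the win indicator for ordering
  # (i, k) at q equals the indicator for (k, i) at 1 - q
  win <- function(i, k, q) {
    f_ind <- q * pool$F_induced[i] + (1 - q) * pool$F_induced[k]
    f_con <- max(q * pool$curves[, i] + (1 - q) * pool$curves[, k])
    f_ind > f_con
  }
  for (q in c(0.2, 0.35, 0.5)) {
    expect_identical(win(1, 2, q), win(2, 1, 1 - q))
    expect_identical(win(2, 1, q), win(1, 2, 1 - q))
  }
})

test_that("multi-environment sampling validates its inputs", {
  pool <- make_pool(F_induced = c(0.5, 0.5),
                    curves = cbind(c(0.6, 0.6), c(0.6, 0.6)),
                    grid = c(0.1, 0.2))
  expect_error(sample_multi_environment(pool, j = 3), "pool size")
  expect_error(sample_multi_environment(pool, j = 1, q = 0.5), "exactly one")
  expect_error(sample_multi_environment(pool, q = 1.5), "0, 1")
})

test_that("the unit perturbation in a gamma scan changes nothing", {
  cells <- data.frame(density = c(5, 40), patchiness = c(1, 40))
  lone <- gamma_scan(imd_params(), gamma_values = 1, k0_values = 0.1,
                     cells = cells, size = 30, walk_cfg = small_walks(),
                     seed = 6)
  pair <- gamma_scan(imd_params(), gamma_values = c(0.5, 1),
                     k0_values = 0.1, cells = cells, size = 30,
                     walk_cfg = small_walks(), seed = 6)
  expect_equal(lone$piw, pair$piw[pair$gamma == 1])
  expect_equal(attr(pair, "best")$k0, 0.1)
  # pure function of (params, gamma, seeds)
  again <- gamma_scan(imd_params(), gamma_values = c(0.5, 1),
                      k0_values = 0.1, cells = cells, size = 30,
                      walk_cfg = small_walks(), seed = 6)
  expect_equal(as.data.frame(pair), as.data.frame(again))
})

test_that("delta scans partition environments and respect knockouts", {
  cells <- data.frame(density = c(10, 60, 120), patchiness = c(1, 6, 120))
  lone <- delta_scan(imd_params(), delta_values = 1, k0_values = 0.1,
                     cells = cells, size = 30, walk_cfg = small_walks(),
                     seed = 7)
  expect_true(all(lone$per_environment$best_delta == 1))
  scan <- delta_scan(imd_params(), delta_values = c(1, 2, 4, 10),
                     k0_values = c(0.1, 0.5), cells = cells, size = 30,
                     walk_cfg = small_walks(), seed = 7)
  sums <- tapply(scan$counts$n_environments, scan$counts$k0, sum)
  expect_true(all(sums == nrow(cells)))
  # no repressosome production: Zs cannot matter, ties resolve to delta = 1
  ko <- delta_scan(imd_params(beta5 = 0), delta_values = c(1, 2, 4, 10),
                   k0_values = 0.1, cells = cells[1:2, ], size = 30,
                   walk_cfg = small_walks(), seed = 8)
  per_env <- split(ko$per_environment$fitness,
                   ko$per_environment$density)
  for (f in per_env) expect_true(all(f == f[1]))
  expect_true(all(ko$per_environment$best_delta == 1))
  expect_error(delta_scan(imd_params(), delta_values = c(2, 4),
                          k0_values = 0.1, cells = cells), "include 1")
})
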