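# exact stochastic simulation: propensities, trajectories, ensembles

test_that("propensities follow the falling-factorial V-power law", {
  m <- parse_model("X + X -> EMPTY : h")
  expect_equal(compute_propensities(m, c(X = 5), list(h = 1), V = 10), 2)
  expect_equal(compute_propensities(m, c(X = 1), list(h = 1), V = 10), 0)
  m2 <- parse_model("X -> EMPTY : d")
  for (V in c(1, 10, 1000)) {
    expect_equal(compute_propensities(m2, c(X = 7), list(d = 2), V), 14)
  }
  expect_error(compute_propensities(m2, c(X = -1), list(d = 1), 1),
               "non-negative")
})

test_that("trajectories are reproducible and structurally valid", {
  bd <- load_fixture("birth_death")
  a <- ssa_trajectory(bd$model, c(X = 0), bd$params$default, V = 10,
                      t_max = 5, seed = 42)
  b <- ssa_trajectory(bd$model, c(X = 0), bd$params$default, V = 10,
                      t_max = 5, seed = 42)
  expect_identical(a, b)
  expect_true(all(diff(a$t) >= 0))
  expect_true(all(a$X >= 0))
  expect_identical(a$t[1], 0)
  expect_equal(a$t[nrow(a)], 5)
  # consecutive states differ by one stoichiometry column
  jumps <- diff(a$X)
  jumps <- jumps[jumps != 0]
  expect_true(all(jumps %in% c(-1, 1)))
})

test_that("absorbing states freeze the trajectory", {
  m <- parse_model("X + X -> EMPTY : h")
  tr <- ssa_trajectory(m, c(X = 1), list(h = 1), V = 10, t_max = 4, seed = 1)
  expect_true(all(tr$X == 1))
  expect_equal(tr$t[nrow(tr)], 4)
})

test_that("birth-death matches the Poisson stationary law", {
  bd <- load_fixture("birth_death")
  tr <- ssa_trajectory(bd$model, c(X = 0), bd$params$default, V = 10,
                       t_max = 50, seed = 1)
  avg <- trajectory_time_average(tr, 25, 50)
  expect_lt(abs(avg[["X"]] - 20), 3 * sqrt(20 / 25))  # generous s.e. bound
  ens <- ssa_ensemble(bd$model, c(X = 0), bd$params$default, V = 10,
                      t_max = 20, runs = 400, seed = 2)
  se_mean <- sqrt(20 / 400)
  expect_lt(abs(ens$mean[["X"]] - 20), 3 * se_mean)
  se_var <- 20 * sqrt(2 / 399)  # var of sample variance, Gaussian approx
  expect_lt(abs(ens$covariance[1, 1] - 20), 3 * se_var)
})

test_that("single-run ensembles degenerate correctly", {
  bd <- load_fixture("birth_death")
  ens <- ssa_ensemble(bd$model, c(X = 0), bd$params$default, V = 10,
                      t_max = 2, runs = 1, seed = 9)
  expect_equal(ens$mean[["X"]], unname(ens$final_states[1, 1]))
  expect_true(all(ens$covariance == 0))
})

test_that("two-state chain matches the binomial stationary law (TV < 0.05)", {
  m <- parse_model("X -> Y : r1\nY -> X : r2")
  N <- 10
  ens <- ssa_ensemble(m, c(X = N, Y = 0), list(r1 = 1, r2 = 1), V = N,
                      t_max = 20, runs = 2000, seed = 5)
  emp <- tabulate(ens$final_states[, "X"] + 1, N + 1) / 2000
  tv <- sum(abs(emp - dbinom(0:N, N, 0.5))) / 2
  expect_lt(tv, 0.05)
})

test_that("ensemble covariance is symmetric PSD with consistent mean", {
  bees <- load_fixture("honeybee")
  ens <- ssa_ensemble(bees$model, bees$init$fig6_left,
                      bees$params$fig6_left, V = 50, t_max = 5, runs = 50,
                      seed = 3)
  expect_equal(ens$covariance, t(ens$covariance))
  expect_true(all(eigen(ens$covariance, only.values = TRUE)$values > -1e-8))
  expect_equal(ens$mean, colMeans(ens$final_states))
})

test_that("species-eliminated models simulate through the reference path", {
  red <- load_fixture("honeybee_reduced")$model
  pars <- list(Delta = 0, mu = 3, s = 3, N = 20)
  tr <- ssa_trajectory(red, c(A = 0, B = 0), pars, V = 20, t_max = 3,
                       seed = 11)
  expect_true(all(tr$A + tr$B <= 20))
  expect_true(all(tr$A >= 0 & tr$B >= 0))
})
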