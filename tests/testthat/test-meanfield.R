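# mass-action derivation, integration, fixed points and field sampling

test_that("mass-action drifts match hand derivations", {
  toy <- load_fixture("toy_birth_annihilation")$model
  oc <- derive_odes(toy, "concentrations")
  expect_q_equal(oc$drift$Phi_X, "k*Phi_A - 2*h*Phi_X^2")
  lv <- derive_odes(load_fixture("lotka_volterra")$model, "concentrations")
  expect_q_equal(lv$drift$Phi_X, "alpha*Phi_A*Phi_X - beta*Phi_X*Phi_Y")
  expect_q_equal(lv$drift$Phi_Y, "beta*Phi_X*Phi_Y - gamma*Phi_Y")
})

test_that("scalar integration reproduces the exponential decay law", {
  tr <- integrate_odes(ode_system(x = "-x"), c(x = 1), list(), t_end = 1,
                       n_points = 11L)
  expect_equal(tr$x[11], exp(-1), tolerance = 1e-6)
  expect_s3_class(tr, "rxn_trajectory")
  expect_identical(nrow(tr), 11L)
})

test_that("integration reports unbound parameters and blow-up times", {
  expect_error(integrate_odes(ode_system(x = "-k*x"), c(x = 1), list(),
                              t_end = 1), "unbound")
  expect_error(
    suppressWarnings(integrate_odes(ode_system(x = "x^2"), c(x = 1), list(),
                                    t_end = 2)),
    "t = ")
})

test_that("closed-model conservation holds along trajectories", {
  bees <- parse_model(honeybee_text())
  odes <- derive_odes(bees, "counts")
  pars <- honeybee_rate_params(mu = 3, Delta = 0.4, s = 2)
  tr <- integrate_odes(odes, c(U = 50, A = 0, B = 0), pars, t_end = 10)
  total <- tr$U + tr$A + tr$B
  expect_lt(max(abs(total - 50)) / 50, 1e-6)
})

test_that("symbolic Jacobian agrees with numerical differentiation", {
  odes <- derive_odes(load_fixture("brusselator")$model, "concentrations")
  pars <- load_fixture("brusselator")$params$fig3_left
  fns <- rxnscale:::ode_functions(odes, pars)
  set.seed(42)
  for (i in 1:20) {
    x <- runif(2, 0.2, 3)
    J <- fns$J(x)
    eps <- 1e-6
    for (j in 1:2) {
      dx <- numeric(2); dx[j] <- eps
      num <- (fns$f(x + dx) - fns$f(x - dx)) / (2 * eps)
      expect_lt(max(abs(num - J[, j]) / pmax(abs(J[, j]), 1)), 1e-5)
    }
  }
})

test_that("1-D fixed points match polynomial root enumeration", {
  fp <- find_fixed_points(ode_system(x = "x*(1 - x)"), list(), -0.5, 1.5)
  expect_identical(nrow(fp), 2L)
  expect_equal(sort(fp$x), c(0, 1), tolerance = 1e-9)
  expect_identical(fp$classification[order(fp$x)], c("unstable", "stable"))

  # random cubics against the independent polyroot oracle
  set.seed(7)
  for (i in 1:10) {
    co <- round(runif(4, -3, 3), 2)
    if (abs(co[4]) < 0.2) co[4] <- 1
    expr <- sprintf("%f + %f*x + %f*x^2 + %f*x^3", co[1], co[2], co[3], co[4])
    roots <- polyroot(co)
    real <- sort(Re(roots[abs(Im(roots)) < 1e-8]))
    real <- real[real >= -10 & real <= 10]
    fp <- find_fixed_points(ode_system(x = expr), list(), -10, 10)
    expect_equal(nrow(fp), length(real))
    if (length(real) > 0) expect_equal(sort(fp$x), real, tolerance = 1e-6)
  }
})

test_that("planar fixed-point structure matches the published portraits", {
  br <- load_fixture("brusselator")
  fp <- find_fixed_points(derive_odes(br$model, "concentrations"),
                          br$params$fig3_left, lower = c(0, 0),
                          upper = c(6, 6))
  expect_identical(sum(fp$classification == "stable"), 1L)
  expect_equal(unlist(fp[fp$classification == "stable", c("Phi_X", "Phi_Y")]),
               c(Phi_X = 2, Phi_Y = 1), tolerance = 1e-6)
})

test_that("field sampling honours the shape contract and equilibria", {
  lv <- load_fixture("lotka_volterra")
  odes <- derive_odes(lv$model, "concentrations")
  pars <- lv$params$fig4_upper_left
  fns <- rxnscale:::ode_functions(odes, pars)
  expect_equal(fns$f(c(1, 1)), c(2, 0), tolerance = 1e-12,
               ignore_attr = TRUE)
  fld <- sample_field(odes, pars, lower = c(0.1, 0.1), upper = c(3, 3),
                      n = 10, include_fixed_points = TRUE)
  expect_identical(nrow(fld), 100L)
  expect_true(all(is.finite(as.matrix(fld))))
  fp <- attr(fld, "fixed_points")
  for (i in seq_len(nrow(fp))) {
    expect_lt(max(abs(fns$f(as.numeric(fp[i, odes$variables])))), 1e-8)
  }
  # >2 dimensions are rejected with advice
  bees <- derive_odes(parse_model(honeybee_text()), "counts")
  expect_error(sample_field(bees, list(), 0, 1), "substitute")
})

test_that("Brusselator regimes split as published", {
  br <- load_fixture("brusselator")
  odes <- derive_odes(br$model, "concentrations")
  tr <- integrate_odes(odes, br$init$fig3, br$params$fig3_left, t_end = 30,
                       n_points = 301L)
  late <- tr[tr$t > 27, ]
  expect_lt(max(apply(late[, -1], 2, function(x) diff(range(x)))), 1e-3)
  tr2 <- integrate_odes(odes, br$init$fig3, br$params$fig3_right, t_end = 30,
                        n_points = 1201L)
  post <- tr2$Phi_X[tr2$t > 10]
  peaks <- post[which(diff(sign(diff(post))) == -2) + 1]
  expect_gte(length(peaks), 3L)
  expect_lt(diff(range(peaks)) / mean(peaks), 0.05)
})
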