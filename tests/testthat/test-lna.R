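# system-size expansion, moments, stationary covariance, correlations

toy_lnr <- function() {
  van_kampen_expand(derive_master_equation(
    load_fixture("toy_birth_annihilation")$model))
}

test_that("the toy-model expansion reproduces the published linear FPE", {
  lnr <- toy_lnr()
  expect_q_equal(lnr$macroscopic$drift$Phi_X, "k*Phi_A - 2*h*Phi_X^2")
  expect_q_equal(lnr$A[[1, 1]], "-4*h*Phi_X")
  expect_q_equal(lnr$B[[1, 1]], "k*Phi_A + 4*h*Phi_X^2")
  # the four printed coefficients of the order-V^0 equation
  expect_equal(fpe_coefficient(lnr, c(X = 2), c(k = 1, Phi_A = 1)), 0.5)
  expect_equal(fpe_coefficient(lnr, c(X = 2), c(h = 1, Phi_X = 2)), 2)
  expect_equal(fpe_coefficient(lnr, c(X = 1), c(h = 1, Phi_X = 1, eta_X = 1)), 4)
  expect_equal(fpe_coefficient(lnr, NULL, c(h = 1, Phi_X = 1)), 4)
})

test_that("one-step decay expands to the textbook drift and diffusion", {
  lnr <- van_kampen_expand(derive_master_equation(
    parse_model("X -> EMPTY : d")))
  expect_q_equal(lnr$macroscopic$drift$Phi_X, "-d*Phi_X")
  expect_q_equal(lnr$A[[1, 1]], "-d")
  expect_q_equal(lnr$B[[1, 1]], "d*Phi_X")
})

test_that("A equals the Jacobian of the macroscopic flow for every fixture", {
  for (nm in c("toy_birth_annihilation", "brusselator", "lotka_volterra",
               "birth_death")) {
    lnr <- van_kampen_expand(derive_master_equation(load_fixture(nm)$model))
    K <- length(lnr$species)
    for (i in seq_len(K)) for (j in seq_len(K)) {
      expect_q_equal(lnr$A[[i, j]],
                     lnr$macroscopic$jacobian[[i]][[j]])
    }
  }
})

test_that("macroscopic equations equal the mass-action concentration ODEs", {
  red <- load_fixture("honeybee_reduced")$model
  lnr <- van_kampen_expand(derive_master_equation(red))
  oc <- derive_odes(red, "concentrations")
  for (v in oc$variables) {
    # the conserved total is the whole population in the expansion
    ref <- rxnscale:::q_subst_sym(oc$drift[[v]], "N", rxnscale:::q_const(1))
    expect_q_equal(lnr$macroscopic$drift[[v]], ref)
  }
})

test_that("moment equations take the canonical A/B form", {
  lnr <- toy_lnr()
  ms <- moment_equations(lnr)
  expect_q_equal(ms$moments[["<eta_X>"]][["<eta_X>"]], "-4*h*Phi_X")
  expect_q_equal(ms$moments[["<eta_X eta_X>"]][["<eta_X eta_X>"]],
                 "-8*h*Phi_X")
  expect_q_equal(ms$moments[["<eta_X eta_X>"]][["1"]],
                 "k*Phi_A + 4*h*Phi_X^2")

  red <- van_kampen_expand(derive_master_equation(
    load_fixture("honeybee_reduced")$model))
  ms2 <- moment_equations(red)
  expect_length(ms2$first, 2L)
  expect_length(ms2$second, 3L)
  # d<eta_i>/dt = sum_j A_ij <eta_j> term by term
  eta <- red$eta
  for (i in 1:2) for (j in 1:2) {
    got <- ms2$moments[[rxnscale:::moment_label(eta[i])]][[
      rxnscale:::moment_label(eta[j])]]
    if (is.null(got)) got <- rxnscale:::q_const(0)
    expect_q_equal(got, red$A[[i, j]])
  }
  # d<eta_i eta_j>/dt = sum_k A_ik <eta_k eta_j> + A_jk <eta_i eta_k> + B_ij
  lab2 <- function(a, b) rxnscale:::moment_label(eta[min(a, b)], eta[max(a, b)])
  for (i in 1:2) for (j in i:2) {
    terms <- ms2$moments[[lab2(i, j)]]
    const <- if (is.null(terms[["1"]])) rxnscale:::q_const(0) else terms[["1"]]
    expect_q_equal(const, red$B[[i, j]])
    for (k in 1:2) for (l in k:2) {
      want <- rxnscale:::q_const(0)
      for (kk in 1:2) {
        if (lab2(kk, j) == lab2(k, l)) want <- rxnscale:::q_add(want, red$A[[i, kk]])
        if (lab2(i, kk) == lab2(k, l)) want <- rxnscale:::q_add(want, red$A[[j, kk]])
      }
      got <- terms[[lab2(k, l)]]
      if (is.null(got)) got <- rxnscale:::q_const(0)
      expect_q_equal(got, want)
    }
  }
})

test_that("stationary covariance solves the Lyapunov equation", {
  lnr <- toy_lnr()
  cv <- stationary_covariance(lnr, c(X = 1 / sqrt(2)),
                              params = list(k = 1, h = 1, Phi_A = 1))
  expect_equal(cv$C[1, 1], 3 / (8 * (1 / sqrt(2))), tolerance = 1e-10)
  expect_equal(cv$C[1, 1], 0.53033, tolerance = 1e-5)
  expect_lt(cv$lyapunov_residual, 1e-8)
  # closed form agrees
  expect_equal(rxnscale:::q_eval(cv$symbolic_C[[1, 1]],
                                 list(k = 1, h = 1, Phi_A = 1,
                                      Phi_X = 1 / sqrt(2))),
               cv$C[1, 1], tolerance = 1e-10)
})

test_that("birth-death fluctuations are Poissonian (C = Phi*)", {
  bd <- load_fixture("birth_death")$model
  lnr <- van_kampen_expand(derive_master_equation(bd))
  b <- 2; d <- 1
  cv <- stationary_covariance(lnr, c(X = b / d), params = list(b = b, d = d))
  expect_equal(cv$C[1, 1], b / d, tolerance = 1e-10)
  # and a zero diffusion matrix yields zero covariance
  dec <- van_kampen_expand(derive_master_equation(parse_model("X -> EMPTY : d")))
  cv0 <- stationary_covariance(dec, c(X = 0), params = list(d = 1))
  expect_equal(cv0$C[1, 1], 0, tolerance = 1e-12)
})

test_that("unstable fixed points are rejected for stationary noise", {
  lnr <- van_kampen_expand(derive_master_equation(
    parse_model("X + X -> X + X : r\nEMPTY -> X : b")))
  expect_error(stationary_covariance(lnr, c(X = 1), list(r = 1, b = 1)),
               "not stable")
})

test_that("noise correlations decay as an Ornstein-Uhlenbeck process", {
  lnr <- toy_lnr()
  cv <- stationary_covariance(lnr, c(X = 1 / sqrt(2)),
                              params = list(k = 1, h = 1, Phi_A = 1))
  nc <- noise_correlation(cv, c(0, 0.5, 1, 2))
  expect_equal(nc$correlation[nc$lag == 0], cv$C[1, 1])
  expect_equal(nc$correlation[nc$lag == 0.5],
               0.53033 * exp(-4 * (1 / sqrt(2)) * 0.5), tolerance = 1e-4)
  expect_true(all(diff(nc$correlation[order(nc$lag)]) < 0))
  expect_error(noise_correlation(cv, -1), "non-negative")
})

test_that("covariance ellipse axes are orthonormal", {
  br <- load_fixture("brusselator")
  lnr <- van_kampen_expand(derive_master_equation(br$model))
  cv <- stationary_covariance(lnr, c(X = 2, Y = 1), br$params$fig3_left)
  V <- cv$ellipse$axes
  expect_equal(t(V) %*% V, diag(2), tolerance = 1e-10)
  expect_true(all(cv$ellipse$radii >= 0))
  expect_lt(cv$lyapunov_residual, 1e-8)
})
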