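# continuation, special-point detection, branch switching, diagrams

test_that("a linear system continues as a single clean stable branch", {
  br <- continue_branch(ode_system(x = "mu - x"), "mu", list(),
                        c(x = -2), -2, range = c(-2, 2))
  expect_identical(nrow(attr(br, "special_points")), 0L)
  expect_true(all(br$stable))
  expect_lt(max(abs(br$x - br$param)), 1e-6)
})

test_that("normal forms locate their singularities to 1e-3", {
  fold <- continue_branch(ode_system(x = "mu + x^2"), "mu", list(),
                          c(x = -1), -1, range = c(-2, 0.5))
  sp <- attr(fold, "special_points")
  expect_true(any(sp$kind == "LP" & abs(sp$param) < 1e-3))
  pitch <- continue_branch(ode_system(x = "mu * x - x^3"), "mu", list(),
                           c(x = 0), -1, range = c(-1, 1))
  sp2 <- attr(pitch, "special_points")
  expect_true(any(sp2$kind == "BP" & abs(sp2$param) < 1e-3))
  trans <- continue_branch(ode_system(x = "mu * x - x^2"), "mu", list(),
                           c(x = 0), -1, range = c(-1, 1))
  sp3 <- attr(trans, "special_points")
  expect_true(any(sp3$kind == "BP" & abs(sp3$param) < 1e-3))
})

test_that("every special point is a refined equilibrium", {
  br <- continue_branch(ode_system(x = "mu + x^2"), "mu", list(),
                        c(x = -1), -1, range = c(-2, 0.5))
  sp <- attr(br, "special_points")
  for (i in seq_len(nrow(sp))) {
    expect_lt(abs(sp$param[i] + sp$x[i]^2), 1e-8)
  }
  # fold test: tangent parameter component changes sign across the LP
  below <- br[br$param < -1e-4, ]
  expect_true(any(!below$stable) && any(below$stable))
})

test_that("branch switching follows the pitchfork limbs symmetrically", {
  pitch <- continue_branch(ode_system(x = "mu * x - x^3"), "mu", list(),
                           c(x = 0), -1, range = c(-1, 1))
  sw <- switch_branch(pitch)
  post <- sw[sw$param > 0.05, ]
  expect_gt(nrow(post), 0L)
  expect_lt(max(abs(post$x^2 - post$param)), 1e-4)
  expect_true(all(post$stable))
  # switching demands a BP
  fold <- continue_branch(ode_system(x = "mu + x^2"), "mu", list(),
                          c(x = -1), -1, range = c(-2, 0.5))
  expect_error(switch_branch(fold), "no branch point")
})

test_that("missing equilibria fall back to integration", {
  # start far from the branch: refinement fails, integration succeeds
  br <- continue_branch(ode_system(x = "mu - x^3"), "mu", list(),
                        c(x = 40), 1, range = c(0.5, 2))
  expect_gt(nrow(br), 5L)
  expect_lt(max(abs(br$x^3 - br$param)), 1e-6)
})

test_that("the stop-signal diagrams have the published structure", {
  fx <- load_fixture("honeybee_reduced")
  # pitchfork with symmetric limbs
  dg <- build_diagram(fx$model, "s", "A - B", params = fx$params$fig5_left,
                      range = c(0.5, 5), lower = 0, upper = 1)
  g <- glance(dg)
  expect_gte(g$n_bp, 1L)
  sbp <- min(dg$special_points$param[dg$special_points$kind == "BP"])
  expect_equal(sbp, 4 * 4^3 / (4^2 - 1)^2, tolerance = 1e-3)  # 4 mu^3/(mu^2-1)^2
  long <- tidy(dg)
  post <- long[long$param > sbp + 0.5 & long$stable, ]
  expect_gt(max(post$response), 0.2)
  expect_lt(min(post$response), -0.2)
  # mirror symmetry of the two limbs
  hi <- sort(post$response[post$response > 0])
  lo <- sort(-post$response[post$response < 0])
  expect_lt(abs(median(hi) - median(lo)), 0.05)

  # unfolding: limit point only
  dg2 <- build_diagram(fx$model, "s", "A - B", params = fx$params$fig5_centre,
                       range = c(0.5, 5), lower = 0, upper = 1)
  g2 <- glance(dg2)
  expect_identical(g2$n_bp, 0L)
  expect_gte(g2$n_lp, 1L)

  # hysteresis in the quality difference
  dg3 <- build_diagram(fx$model, "Delta", "A - B",
                       params = fx$params$fig5_right, range = c(-1, 1),
                       lower = 0, upper = 1)
  sp3 <- dg3$special_points[dg3$special_points$kind == "LP", ]
  expect_identical(nrow(sp3), 2L)
  expect_lt(sp3$param[1] * sp3$param[2], 0)  # LPs bracket Delta = 0
})
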