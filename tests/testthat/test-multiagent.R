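# interaction topologies, state-machine compilation, and the agent engine

test_that("topology kinds satisfy their structural contracts", {
  top <- build_topology("complete", n = 5)
  expect_identical(topology_degrees(top), rep(4L, 5))
  e0 <- build_topology("erdos_renyi", n = 20, p = 0, seed = 1)
  expect_identical(sum(topology_degrees(e0)), 0L)
  e1 <- build_topology("erdos_renyi", n = 20, p = 1, seed = 1)
  expect_identical(topology_degrees(e1), rep(19L, 20))
  # radius beyond the square diagonal makes the geometric graph complete
  g <- build_topology("geometric_static", n = 15, radius = 1.5, seed = 2)
  expect_identical(topology_degrees(g), rep(14L, 15))
  ba <- build_topology("barabasi_albert", n = 30, m = 2, seed = 3)
  expect_identical(length(topology_degrees(ba)), 30L)
  expect_error(build_topology("erdos_renyi", n = 5, p = 2), "p in")
  expect_error(build_topology("geometric_static", n = 5, radius = 0),
               "radius")
})

test_that("topologies and trajectories are seed-reproducible", {
  g1 <- build_topology("erdos_renyi", n = 30, p = 0.2, seed = 7)
  g2 <- build_topology("erdos_renyi", n = 30, p = 0.2, seed = 7)
  expect_identical(g1$adj, g2$adj)
  bees <- load_fixture("honeybee")
  sm <- compile_state_machine(bees$model)
  t1 <- multiagent_trajectory(sm, g1, c(U = 30, A = 0, B = 0),
                              bees$params$fig6_left, t_max = 2, seed = 4)
  t2 <- multiagent_trajectory(sm, g2, c(U = 30, A = 0, B = 0),
                              bees$params$fig6_left, t_max = 2, seed = 4)
  expect_identical(t1, t2)
})

test_that("rule compilation separates spontaneous and interactive", {
  sm <- compile_state_machine(parse_model(honeybee_text()))
  expect_identical(nrow(sm$spontaneous), 4L)
  expect_identical(nrow(sm$interactive), 4L)
  expect_identical(sm$interactive$t1[sm$interactive$s2 == "U" &
                                       sm$interactive$s1 == "A"], "A")
  # non-conserving or reservoir rules are rejected by name
  expect_error(compile_state_machine(
    load_fixture("toy_birth_annihilation")$model), "constant species")
  expect_error(compile_state_machine(parse_model("X -> X + X : r")),
               "number of agents")
  expect_error(compile_state_machine(parse_model("3 X -> 3 X : r")),
               "more than two")
})

test_that("the timestep matches the fastest agent state", {
  sm <- compile_state_machine(parse_model("X -> Y : r"))
  expect_equal(choose_timestep(sm, list(r = 2), safety = 1), 0.5)
  dt1 <- choose_timestep(sm, list(r = 2), safety = 0.5)
  dt2 <- choose_timestep(sm, list(r = 4), safety = 0.5)
  expect_equal(dt1 / dt2, 2)  # doubling rates halves dt
  bees <- compile_state_machine(parse_model(honeybee_text()))
  pars <- honeybee_rate_params(3, 0, 3)
  dt <- choose_timestep(bees, pars, safety = 0.5)
  # every per-step probability the tables realise is below safety
  tab <- rxnscale:::agent_tables(bees, pars, dt, safety = 0.5)
  expect_true(all(tab$spont[, 3] <= 0.5 + 1e-12))
  expect_true(all(tab$inter[, 5] <= 0.5 + 1e-12))
})

test_that("inert dynamics leave counts constant; totals are conserved", {
  m <- parse_model("X -> X : r")
  sm <- compile_state_machine(m)
  tr <- multiagent_trajectory(sm, build_topology("complete", n = 12),
                              c(X = 12), list(r = 1), t_max = 2, seed = 1)
  expect_true(all(tr$X == 12))
  bees <- load_fixture("honeybee")
  smb <- compile_state_machine(bees$model)
  trb <- multiagent_trajectory(smb, build_topology("complete", n = 40),
                               c(U = 40, A = 0, B = 0),
                               bees$params$fig6_left, t_max = 5, seed = 2)
  expect_true(all(trb$U + trb$A + trb$B == 40))
})

test_that("complete-graph agents agree with the SSA and the mean field", {
  bees <- load_fixture("honeybee")
  sm <- compile_state_machine(bees$model)
  pars <- bees$params$fig6_left
  # ensemble mean against the ODE over the deterministic transient
  top <- build_topology("complete", n = 500)
  ens <- multiagent_ensemble(sm, top, c(U = 500, A = 0, B = 0), pars,
                             t_max = 3, runs = 10, seed = 1, safety = 0.2)
  odes <- derive_odes(load_fixture("honeybee_reduced")$model, "counts")
  tr <- integrate_odes(odes, c(A = 0, B = 0),
                       list(Delta = 0, mu = 3, s = 3, N = 1),
                       t_end = 3, n_points = nrow(ens$grid))
  for (v in c("A", "B")) {
    ode_v <- tr[[v]] * 500
    rel <- sqrt(mean((ens$grid[[v]] - ode_v)^2)) / sqrt(mean(ode_v^2))
    expect_lt(rel, 0.1)
  }
  # final-state means against the SSA at matched time
  top50 <- build_topology("complete", n = 50)
  ma <- multiagent_ensemble(sm, top50, c(U = 50, A = 0, B = 0), pars,
                            t_max = 10, runs = 100, seed = 2, safety = 0.2)
  ss <- ssa_ensemble(bees$model, c(U = 50, A = 0, B = 0), pars, V = 50,
                     t_max = 10, runs = 100, seed = 3)
  se <- sqrt(diag(ss$covariance) / 100 + diag(ma$covariance) / 100)
  expect_true(all(abs(ss$mean - ma$mean) < 3 * se))
})

test_that("symmetry breaking survives embedding in the moving plane", {
  bees <- load_fixture("honeybee")
  sm <- compile_state_machine(bees$model)
  top <- build_topology("geometric_dynamic", n = 50, radius = 0.2, seed = 5)
  broken <- 0L
  for (r in 1:10) {
    tr <- multiagent_trajectory(sm, top, c(U = 50, A = 0, B = 0),
                                bees$params$fig6_left, t_max = 10,
                                seed = 100 + r)
    fin <- tr[nrow(tr), ]
    if (abs(fin$A - fin$B) / 50 > 0.2) broken <- broken + 1L
  }
  expect_gte(broken, 8L)
})

test_that("dynamic geometric runs can export agent positions", {
  m <- parse_model("X -> Y : r\nY -> X : q")
  sm <- compile_state_machine(m)
  top <- build_topology("geometric_dynamic", n = 8, radius = 0.3, seed = 1)
  tr <- multiagent_trajectory(sm, top, c(X = 8, Y = 0), list(r = 1, q = 1),
                              t_max = 1, seed = 2, record_positions = TRUE)
  pos <- attr(tr, "positions")
  expect_identical(dim(pos), c(nrow(tr), 16L))
  expect_true(all(pos >= 0 & pos <= 1))
})
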