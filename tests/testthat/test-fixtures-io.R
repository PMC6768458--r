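# packaged fixtures, reference parameter sets, serialization

test_that("every fixture parses and matches its packaged rule file", {
  for (nm in c("honeybee", "brusselator", "lotka_volterra",
               "toy_birth_annihilation", "birth_death")) {
    fx <- load_fixture(nm)
    expect_s3_class(fx$model, "reaction_model")
    path <- system.file("extdata", paste0(nm, ".rxn"), package = "rxnscale")
    expect_identical(model_text(read_model(path)), model_text(fx$model))
  }
  expect_error(load_fixture("nonesuch"), "unknown fixture")
})

test_that("reference parameter sets hold the published caption values", {
  expect_identical(load_fixture("honeybee_reduced")$params$fig4_lower_right,
                   list(Delta = 0.0, mu = 3.0, s = 10.0, N = 20))
  b <- load_fixture("brusselator")$params
  expect_identical(b$fig3_left[c("chi", "delta", "gamma", "xi")],
                   list(chi = 2.0, delta = 2.0, gamma = 2.0, xi = 2.0))
  expect_identical(b$fig3_left$Phi_beta, 2.0)
  expect_identical(b$fig3_right$Phi_beta, 5.5)
  expect_identical(b$fig3_left$V, 10)
  lv <- load_fixture("lotka_volterra")$params$fig4_upper_left
  expect_identical(lv, list(alpha = 2.0, beta = 2.0, gamma = 2.0, Phi_A = 2.0))
  hb <- load_fixture("honeybee")$params$fig6_left
  expect_identical(hb[c("V", "t_max", "runs")], list(V = 50, t_max = 10, runs = 10))
  expect_identical(unlist(hb[c("g_A", "g_B", "s")]),
                   c(g_A = 3, g_B = 3, s = 3))
})

test_that("the reduced model is the honeybee model after its substitutions", {
  red <- load_fixture("honeybee_reduced")$model
  manual <- substitute_model(
    substitute_model(
      substitute_model(parse_model(honeybee_text()), "U = N - A - B"),
      "a_A = 1/v_A, a_B = 1/v_B, g_A = v_A, g_B = v_B, r_A = v_A, r_B = v_B"),
    "v_A = mu + Delta/2, v_B = mu - Delta/2")
  o1 <- derive_odes(red, "counts")
  o2 <- derive_odes(manual, "counts")
  for (v in o1$variables) expect_q_equal(o1$drift[[v]], o2$drift[[v]])
})

test_that("trajectories export to CSV with the documented schema", {
  tr <- integrate_odes(ode_system(x = "-x"), c(x = 1), list(), 1,
                       n_points = 21L)
  path <- tempfile(fileext = ".csv")
  export_results(tr, path)
  back <- utils::read.csv(path)
  expect_identical(names(back), c("t", "x"))
  expect_identical(nrow(back), 21L)
})

test_that("covariance results export to JSON and round-trip exactly", {
  toy <- load_fixture("toy_birth_annihilation")$model
  lnr <- van_kampen_expand(derive_master_equation(toy))
  cv <- stationary_covariance(lnr, c(X = 1 / sqrt(2)),
                              params = list(k = 1, h = 1, Phi_A = 1))
  path <- tempfile(fileext = ".json")
  export_results(cv, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_setequal(names(back),
                  c("species", "A", "B", "C", "fixed_point", "ellipse",
                    "lyapunov_residual", "metadata"))
  expect_identical(as.numeric(back$C), cv$C[1, 1])  # bit-exact float
  expect_identical(back$metadata$class, "covariance_result")
})

test_that("ensembles export both tabular and structured forms", {
  bd <- load_fixture("birth_death")
  ens <- ssa_ensemble(bd$model, c(X = 0), bd$params$default, V = 5,
                      t_max = 2, runs = 5, seed = 1)
  csv <- tempfile(fileext = ".csv")
  export_results(ens, csv)
  back <- utils::read.csv(csv)
  expect_identical(names(back), c("run", "species", "count"))
  expect_identical(nrow(back), 5L)
  js <- tempfile(fileext = ".json")
  export_results(ens, js)
  parsed <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_identical(parsed$runs, 5L)
  expect_identical(parsed$metadata$seed, 1L)
})
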