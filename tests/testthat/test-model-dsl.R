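# rule-set grammar, model algebra and stoichiometry

test_that("toy model parses with reservoir species and coefficients", {
  m <- parse_model("(A) -> X : k\nX + X -> EMPTY : h")
  expect_identical(dynamic_species(m), "X")
  expect_identical(rxnscale:::constant_species(m), "A")
  expect_length(m$reactions, 2L)
  expect_identical(m$reactions[[2]]$reactants, c(X = 2L))
  expect_length(m$reactions[[2]]$products, 0L)
  expect_setequal(m$parameters, c("k", "h"))
  S <- stoichiometry(m)
  expect_identical(as.integer(S), c(1L, -2L))
})

test_that("net-zero identity rules are legal and inert", {
  m <- parse_model("X -> X : r")
  expect_identical(as.integer(stoichiometry(m)), 0L)
  odes <- derive_odes(m)
  expect_true(rxnscale:::q_is_zero(odes$drift$X))
})

test_that("the eight-rule stop-signal model parses as published", {
  m <- parse_model(honeybee_text())
  expect_identical(m$species$name, c("U", "A", "B"))
  expect_length(m$reactions, 8L)
  expect_setequal(m$parameters,
                  c("g_A", "g_B", "a_A", "a_B", "r_A", "r_B", "s"))
  S <- stoichiometry(m)
  expect_identical(dim(S), c(3L, 8L))
  expect_true(all(colSums(S) == 0L))  # closed system
})

test_that("grammar errors carry line numbers; duplicates warn", {
  expect_error(parse_model("X -> Y"), "line 1")
  expect_error(parse_model("X -> Y : r\nX + -> Z : q"), "line 2")
  expect_error(parse_model("0 X -> Y : r"), ">= 1")
  expect_error(parse_model("V -> X : r"), "reserved")
  expect_error(parse_model("Phi_X -> X : r"), "reserved")
  expect_error(parse_model("X -> Y : X"), "species symbol")
  expect_warning(parse_model("X -> Y : r\nX -> Y : r"), "duplicate")
})

test_that("serialization round-trips to a symbolically identical model", {
  for (nm in c("honeybee", "brusselator", "lotka_volterra",
               "toy_birth_annihilation", "birth_death")) {
    m <- load_fixture(nm)$model
    m2 <- parse_model(model_text(m))
    expect_identical(m2$species, m$species)
    expect_identical(stoichiometry(m2), stoichiometry(m))
    for (j in seq_along(m$reactions)) {
      expect_q_equal(m2$reactions[[j]]$rate, m$reactions[[j]]$rate)
    }
  }
})

test_that("species elimination reduces the dynamic dimension", {
  m <- parse_model(honeybee_text())
  m2 <- substitute_model(m, "U = N - A - B")
  expect_identical(dynamic_species(m2), c("A", "B"))
  expect_identical(m2$conserved_total, "N")
  expect_true("N" %in% m2$parameters)
  # input untouched
  expect_identical(dynamic_species(m), c("U", "A", "B"))
  expect_identical(dim(stoichiometry(m2)), c(2L, 8L))
})

test_that("substitution is order-consistent and identity-stable", {
  m <- parse_model(honeybee_text())
  joint <- substitute_model(m, c("g_A = v_A", "v_A = mu + Delta/2"))
  seq2 <- substitute_model(substitute_model(m, "g_A = v_A"),
                           "v_A = mu + Delta/2")
  for (j in seq_along(m$reactions)) {
    expect_q_equal(joint$reactions[[j]]$rate, seq2$reactions[[j]]$rate)
  }
  ident <- substitute_model(m, "s = s")
  for (j in seq_along(m$reactions)) {
    expect_q_equal(ident$reactions[[j]]$rate, m$reactions[[j]]$rate)
  }
})

test_that("substitution errors are informative", {
  m <- parse_model(honeybee_text())
  expect_error(substitute_model(m, "Z = N - A"), "neither a species nor")
  expect_error(substitute_model(m, "g_A = A"), "species symbol")
})

test_that("model files read and write through the same grammar", {
  path <- system.file("extdata", "brusselator.rxn", package = "rxnscale")
  expect_true(nzchar(path))
  m <- read_model(path)
  ref <- load_fixture("brusselator")$model
  expect_identical(m$species, ref$species)
  tmp <- tempfile(fileext = ".rxn")
  write_model(m, tmp)
  expect_identical(model_text(read_model(tmp)), model_text(ref))
})
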