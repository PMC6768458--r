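# shared test helpers

expect_q_equal <- function(a, b) {
  if (is.character(a)) a <- rxnscale:::q_parse(a)
  if (is.character(b)) b <- rxnscale:::q_parse(b)
  expect_true(rxnscale:::q_equal(a, b))
}

honeybee_text <- function() {
  paste("U -> A : g_A", "U -> B : g_B", "A -> U : a_A", "B -> U : a_B",
        "A + U -> A + A : r_A", "B + U -> B + B : r_B",
        "A + B -> A + U : s", "A + B -> B + U : s", sep = "\n")
}

# published right-hand sides of the reduced stop-signal equations
eq1_drift <- function() {
  list(
    A = rxnscale:::q_parse(paste(
      "-A*B*s + A*(Delta/2 + mu)*(-A - B + N)",
      "- A/(Delta/2 + mu) + (Delta/2 + mu)*(-A - B + N)")),
    B = rxnscale:::q_parse(paste(
      "-A*B*s + B*(-Delta/2 + mu)*(-A - B + N)",
      "- B/(-Delta/2 + mu) + (-Delta/2 + mu)*(-A - B + N)"))
  )
}

# dense CME generator on the lattice of a closed two-species chain; states
# indexed by the count of the first species 0..N
two_state_generator <- function(model, params, N) {
  Q <- matrix(0, N + 1, N + 1)
  for (nx in 0:N) {
    a <- compute_propensities(model, c(X = nx, Y = N - nx), params, V = N)
    if (nx > 0) Q[nx, nx + 1] <- Q[nx, nx + 1] + a[1]      # X -> Y
    if (nx < N) Q[nx + 2, nx + 1] <- Q[nx + 2, nx + 1] + a[2]  # Y -> X
    Q[nx + 1, nx + 1] <- Q[nx + 1, nx + 1] - sum(a)
  }
  Q
}
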