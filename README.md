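# rxnscale

Multiscale analysis of reaction-kinetics models of collective behaviour.

Collective systems — swarms choosing a nest site, chemical networks,
predator–prey communities, opinion dynamics — are naturally recorded as
reaction rules: *who interacts with whom, what they become, and how fast*.
`rxnscale` parses such rule sets from plain text and derives, automatically
and consistently, the mathematics at three scales:

1. **Infinite well-mixed populations** — mass-action ODEs, phase portraits,
   fixed-point classification, and one-parameter bifurcation continuation
   with branch-point (BP) and limit-point (LP) detection and branch
   switching.
2. **Finite well-mixed populations** — the chemical master equation
   ∂P({n};t)/∂t = Σᵢ rᵢ V̄ (Πₖ Eₖ^(αₖ−βₖ) − 1) Πⱼ ((nⱼ))_αⱼ / V̄^αⱼ · P as a
   symbolic object, its van Kampen system-size expansion
   (nₖ = V̄Φₖ + √V̄ ηₖ), the linear-noise drift matrix A and diffusion
   matrix B, moment equations d⟨η⟩/dt = A⟨η⟩,
   dC/dt = AC + CAᵀ + B, stationary covariances from the Lyapunov equation
   AC + CAᵀ + B = 0, noise correlation functions e^{Aτ}C, and exact
   Gillespie stochastic simulation (SSA).
3. **Finite spatial populations** — the rules compiled to per-agent
   probabilistic finite state machines executed in synchronous timesteps on
   complete, Erdős–Rényi, Barabási–Albert, or (static/dynamic) random
   geometric interaction topologies, with the timestep automatically
   matched to the population-level time scale.

A small exact rational-polynomial engine performs all symbolic
manipulation, so derived equations can be compared *symbolically*, not just
numerically.

## A worked example

The honeybee stop-signal model of collective nest-site choice: uncommitted
scouts `U` discover sites A and B, committed scouts recruit, abandon, and
cross-inhibit:

```r
library(rxnscale)

bees <- parse_model("
  U -> A : g_A         # discovery
  U -> B : g_B
  A -> U : a_A         # abandonment
  B -> U : a_B
  A + U -> A + A : r_A # recruitment
  B + U -> B + B : r_B
  A + B -> A + U : s   # cross-inhibitory stop signal
  A + B -> B + U : s
")

reduced <- bees |>
  substitute_model("U = N - A - B") |>
  substitute_model("a_A = 1/v_A, a_B = 1/v_B, g_A = v_A, g_B = v_B,
                    r_A = v_A, r_B = v_B") |>
  substitute_model("v_A = mu + Delta/2, v_B = mu - Delta/2")

derive_odes(reduced, "counts")
#> <ode_system> (counts form)
#>   dA/dt = (-2 * A + ... + 2 * (mu^2 * N))/(Delta + 2 * mu)
#>   dB/dt = (... )/(Delta + -2 * mu)
#> parameters: Delta, mu, N, s
```

With equal-quality sites (`Delta = 0`, `mu = 4`), sweeping the stop-signal
strength `s` reveals the symmetry-breaking pitchfork:

```r
dg <- build_diagram(reduced, "s", "A - B",
                    params = list(Delta = 0, mu = 4, N = 1),
                    range = c(0.5, 5), lower = 0, upper = 1)
glance(dg)
#> # A tibble: 1 x 4
#>   n_branches  n_bp  n_lp n_warnings
#>        <int> <int> <int>      <int>
#> 1          3     1     2          0
dg$special_points[dg$special_points$kind == "BP", "param"]
#> 1.137778        # = 4 mu^3 / (mu^2 - 1)^2 at mu = 4
```

Finite-population noise around a stable state, and the exact simulation
that confirms it:

```r
toy <- load_fixture("toy_birth_annihilation")   # (A) -> X : k ; X + X -> EMPTY : h
lnr <- van_kampen_expand(derive_master_equation(toy$model))
cv  <- stationary_covariance(lnr, c(X = 1/sqrt(2)), params = toy$params$default)
cv$C
#>           X
#> X 0.5303301      # stationary variance of the scaled fluctuation eta_X

ens <- ssa_ensemble(toy$model, c(X = 141), toy$params$default,
                    V = 200, t_max = 20, runs = 400, seed = 1)
var((ens$final_states[, 1] - 200/sqrt(2)) / sqrt(200))
#> [1] 0.52  # within sampling error of 0.5303
```

Agent-based simulation on a moving plane (correlated random walks,
interaction radius 0.2):

```r
sm  <- compile_state_machine(bees)
top <- build_topology("geometric_dynamic", n = 50, radius = 0.2, seed = 1)
tr  <- multiagent_trajectory(sm, top, c(U = 50, A = 0, B = 0),
                             honeybee_rate_params(mu = 3, Delta = 0, s = 3),
                             t_max = 10, seed = 1)
tail(tr, 1)
#>       t     U     A     B
#> 1  10.0     4     39     7   # symmetry broken
```

Every result object has `autoplot()`, and most have `tidy()`/`glance()`
methods. `export_results()` writes CSV/JSON. A thin command-line front end
over these functions lives at `inst/cli/rxnscale.R`
(`Rscript inst/cli/rxnscale.R ssa --model bees.rxn ...`).

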