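---
title: "Multiscale analysis of reaction-kinetics models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale analysis of reaction-kinetics models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rxnscale)
```

`rxnscale` takes a textual reaction-kinetics description of a collective
system and derives its population-level mathematics at three scales that are
consistent with each other at matched time units: deterministic mean-field
equations, Gaussian fluctuation theory around them, and exact or
agent-resolved stochastic simulation. This vignette explains the models and
assumptions behind each stage, the tunable parameters, the numerical choices,
what the synthetic fixture models do and do not emulate, and the known
limitations.

## The rule language and its semantics

A model is a set of rules `LHS -> RHS : rate`. Terms are species names with
optional integer stoichiometric coefficients (`2 X`), `(name)` marks a
*reservoir* species whose abundance is held constant (it enters derived
expressions through its fixed proportion `Phi_name`), and `EMPTY` denotes the
empty side. Rates are arithmetic expressions over parameters only; richer
kinetics (Hill, Michaelis–Menten) are out of scope because the finite-
population machinery below assumes constant interaction rates per reaction.
Reversible reactions are written as two explicit rules, one per direction.
The symbols `V` (system size), `t` (time), and the `Phi_*`/`eta_*` families
(proportions and fluctuation variables) are reserved.

Model algebra happens through `substitute_model()`. A parameter target
rewrites every rate. A species target *eliminates* the species from the
dynamic state: the rules are left untouched and the replacement expression is
applied in all derived expressions (drifts, propensities, master-equation
factors), so the ODE dimension drops by one. When the replacement has the
form `N - (sum of the other species)` with a fresh symbol `N`, that symbol is
recorded as the model's conserved total.

## Scale 1: mean field

`derive_odes()` applies the law of mass action: the drift of species X is
the sum over reactions of net stoichiometry times rate times the product of
reactant abundances raised to their coefficients. Two representations are
offered, matching the two conventions in which such systems are printed:

* **counts form** — raw mass action on count symbols, no system-size
  factors. This is the form in which the reduced stop-signal equations are
  usually printed; with the conserved total set to 1 the counts are
  proportions.
* **concentrations form** — mass action on the proportion symbols
  `Phi_*`. This is the deterministic (infinite-V) limit of the stochastic
  machinery below; the two meet through n = V·Φ.

The symbolic Jacobian is carried alongside, and a test asserts it against
numerical differentiation. Integration uses `deSolve::lsoda` (adaptive
stiff/non-stiff switching) with rtol 1e-8, atol 1e-10.

`find_fixed_points()` uses exact polynomial root enumeration in one
dimension (the drift numerator's roots via `polyroot`, then Newton polish);
otherwise a grid of damped-Newton starts (8 per dimension, interior nodes of
the search box), duplicate merging at 1e-6, and classification from Jacobian
eigenvalue real parts with threshold 1e-9. A point with an eigenvalue inside
the threshold is flagged marginal and conservatively reported unstable.
These values are reproducibility choices, not tuned quantities.

## Scale 1b: bifurcation continuation

Continuation is implemented natively as pseudo-arclength
predictor–corrector: a unit tangent from the full SVD of the extended
Jacobian `[J_x | F_p]`, Newton correction perpendicular to the tangent, and
adaptive steps (initial 1/100 of the parameter range, growing 1.3x to 5x,
halving on failure, at most 2000 steps per direction). Two guards reject
steps that betray a jump onto a different equilibrium sheet: a corrected
point further than three step lengths from its predictor, and a tangent
turning by more than 60 degrees. Without the second guard the corrector can
hop across a narrow fold — the unfolded pitchfork of the stop-signal model
was the motivating case.

Special points use two test functions evaluated between consecutive accepted
points: the parameter component of the tangent (sign change = fold, LP) and
det(J_x) (sign change without a fold = BP; when both fire simultaneously the
point is reported as LP). Each detection is refined by bisection in
arclength to 1e-6 in the parameter. On the fold and pitchfork normal forms
the detected locations are within 1e-3 of the analytic values, which the
test suite asserts. Branch switching at a BP seeds a new continuation along
the second null direction of the extended Jacobian, orthogonalised against
the current branch tangent, attempted in both orientations.

Hopf points are deliberately not detected — only BP/LP are in scope — so
oscillatory regimes (e.g. the Brusselator limit cycle) are established by
integration instead. `build_diagram()` orchestrates equilibrium searches at
five parameter values across the range, continues every distinct equilibrium
(a candidate is a duplicate when its normalised distance to an existing
branch polyline is below 2%), switches at BPs, and evaluates a response
expression — a reactant, sum, or difference — at every point.

## Scale 2: finite populations

`derive_master_equation()` builds the chemical master equation term by term:
reaction i contributes `rate_i V^(1-Σα) (Π_k E_k^(α_k-β_k) - 1)
Π_j ((n_j))_α_j P`, with `((n))_a` the falling factorial and `E_k^m` the
step operator shifting count k by m. The V-power convention makes
unimolecular propensities `rate·n` and bimolecular ones `rate·n(n-1)/V`.
Reservoir species contribute `Phi·V` in place of a dynamic count. For
species-eliminated models the falling factorial of the replacement
expression appears instead, and the conserved total is identified with the
system size (the population is closed with N = V agents, Φ_U = 1-Φ_A-Φ_B);
this identification is what makes the reduced model's expansion match the
full model's.

`van_kampen_expand()` performs the system-size expansion mechanically: the
substitution n = VΦ + √V·η, second-order expansion of every step operator
(E^m = 1 + mV^(-1/2)∂_η + (m²/2)V^(-1)∂²_η), product-rule expansion of the
operators acting on propensity-times-distribution, and collection of powers
of √V. The order-√V terms are required (and asserted) to be η-free
first-derivative terms; they yield the macroscopic equations, which are
verified symbolically to equal the mass-action concentration ODEs. The
order-V⁰ terms form the linear Fokker–Planck equation, from which the drift
matrix A (equal to the macroscopic Jacobian — asserted structurally) and the
symmetric diffusion matrix B are read off. All lower orders are discarded:
this is the linear noise approximation, so the fluctuation theory is
Gaussian and valid near hyperbolic attractors for large V.

Moment equations are obtained honestly from the expansion — integrating the
FPE against η and ηηᵀ by parts — and tested against the canonical forms
d⟨η⟩/dt = A⟨η⟩ and dC/dt = AC + CAᵀ + B. `stationary_covariance()` solves
AC + CAᵀ + B = 0 at a stable fixed point (Kronecker-product linear solve;
closed-form solution via exact symbolic elimination for dimensions ≤ 2,
residual asserted ≤ 1e-8) and reports two ellipses: the principal-axis
(eigen-decomposition of C) 1-σ ellipse, which is the covariance ellipse a
simulation aggregate draws, and the projections of C onto the normalised
eigenvectors of A, reported when those eigenvectors are real. Both are
emitted because for non-normal A the two constructions genuinely differ.
Lagged correlations use the Ornstein–Uhlenbeck identity ⟨η(t+τ)η(t)ᵀ⟩ =
e^(Aτ)C with `Matrix::expm`.

`ssa_trajectory()` is the direct-method stochastic simulation algorithm with
the identical propensity law, implemented in C++ over R's RNG stream, so a
seed fully determines a trajectory. Ensembles decorrelate runs with
sub-seeds derived from (seed, run index). Exactness is tested against the
Poisson stationary law of a birth–death process and a brute-force binomial
stationary distribution of a two-state chain (total variation < 0.05 at
2000 samples), and against the LNA variance of the toy birth/annihilation
model at V = 200.

## Scale 3: spatial populations

`compile_state_machine()` turns rules into a per-agent probabilistic finite
state machine: unimolecular rules become spontaneous transitions,
bimolecular rules pairwise interactive transitions (the two written
reactant positions map onto the two written product positions). Only
agent-count-conserving rules with at most two participants compile; rules
with reservoir species, creation, destruction, or three-body interactions
are rejected by name.

Topologies: complete graph, Erdős–Rényi, Barabási–Albert (via igraph), and
random geometric graphs on the periodic unit square — static, or dynamic
with a correlated random walk (per-step heading change ~ Normal(0, 0.3 rad),
speed 0.01 per step by default) and adjacency recomputed every step.
Periodic boundaries avoid wall-density artefacts; both walk parameters are
user-settable and logged in the topology object.

The timestep is matched to population time automatically:
dt = safety / R_max, with R_max the largest total outgoing rate over agent
states assuming a matching partner is always available, so every per-step
probability rate·dt stays at or below the safety factor (default 0.5).
Each step, agents act in randomised order; an agent draws one uniform
variate against the cumulative list of its spontaneous rules and the
interactive rules matched to one uniformly chosen neighbour, so every
candidate fires with probability exactly rate·dt. For a pair of distinct
states either member may initiate, so each orientation carries rate·dt/2,
keeping the expected pairwise event rate equal to the SSA propensity on the
complete graph; identical-state pairs have one orientation at full rate.
An agent that already took part in a transition this step cannot take part
again — this partner exclusion is the dominant discretisation artefact and
scales with the safety factor. For quantitative cross-scale comparisons the
package's tests therefore run at safety = 0.2; the default 0.5 is kept for
exploratory use where per-step resolution matters less than wall time.

Cross-scale consistency is the validation strategy: on the complete graph
with 500 agents the ensemble-mean trajectory tracks the mean-field solution
within 10% relative RMS over the deterministic transient (t ≤ 3; about 1%
in practice), and at 50 agents the final-state means match 100 SSA runs
within three standard errors at the published horizon t = 10. The
transient window for the ODE comparison is a deliberate choice: with equal
site qualities the deterministic solution stays symmetric while individual
stochastic runs break symmetry, so beyond the transient the ensemble mean
of a bimodalising distribution no longer estimates the ODE state and the
comparison would test nothing.

## The fixture models

* `honeybee` / `honeybee_reduced` — the stop-signal nest-site model:
  discovery (rate = site quality v), abandonment (1/v), recruitment (v),
  and cross-inhibition (s), reparameterised through mean quality mu and
  difference Delta. It exercises symbolic reduction, the pitchfork and its
  unfolding, hysteresis in Delta, anisotropic noise ellipses, and
  deadlock-breaking simulations.
* `brusselator` — autocatalytic oscillator; with all rates 2.0 the stable
  and oscillatory regimes split at Φ_β vs Φ_α², which the integration tests
  verify structurally (convergence vs ≥3 comparable maxima).
* `lotka_volterra` — predator–prey oscillations for phase portraits.
* `toy_birth_annihilation` — `(A) -> X : k`, `X + X -> EMPTY : h`; small
  enough that every master-equation and expansion coefficient is checked
  against hand derivation.
* `birth_death` — Poissonian reference for SSA exactness.

Reference parameter sets are the published figure-caption values and are
golden-tested. Where a caption leaves an initial condition open (the
Brusselator's Φ_Y(0)), the fixture fixes Φ_Y(0) = 1.0 — any positive value
serves the regime tests. These fixtures emulate well-mixed or
geometrically embedded populations with constant per-contact rates; they do
not emulate heterogeneous per-agent rates, state-dependent kinetics, or
three-dimensional arenas, so passing tests say nothing about those settings.

## Numerical choices and degenerate inputs

* Symbolic engine: exact rational-polynomial arithmetic with double
  coefficients; cancellation residues below 1e-10 relative to the largest
  coefficient are cleaned, and symbolic equality cross-multiplies
  denominators, so identities built from dyadic inputs test exactly.
* Problem sizes in the test suite (ensemble counts of 100–2000, V of
  10–1000, five-figure event counts) are chosen so each statistical
  assertion sits at least three standard errors from its oracle while the
  whole suite stays interactive.
* Degenerate inputs: rules with zero net stoichiometry are legal and
  dynamically inert at every scale; an empty propensity vector freezes an
  SSA trajectory; all-zero rates make the agent timestep undefined (an
  error); unstable fixed points are rejected for stationary noise; lags
  must be non-negative.

## Known limitations

Continuation handles systems of dimension ≤ 2 (reduce first by
substitution); codimension-two bifurcations, limit-cycle continuation, and
Hopf detection are out of scope. The linear noise approximation degrades
near bifurcations, exactly where fluctuations are largest — the stop-signal
deadlock at weakly unstable parameters is the cautionary example: with
Δ = 0, μ = 3, s = 3 the deadlock's unstable eigenvalue is ≈ 0.14, so at
system size 50 a noticeable fraction of exact-simulation runs remains
within |A−B|/N ≤ 0.2 of deadlock even at t = 20; qualitative
deadlock-breaking claims at that scale are therefore statements about most
runs, not all runs. The agent engine conserves agent count by construction
and so cannot represent open systems; use the SSA for those.
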