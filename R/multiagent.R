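#' Build an interaction topology
#'
#' Topologies on which a finite population of agents interacts: the complete
#' graph (well-mixed), the Erdos-Renyi random graph, the Barabasi-Albert
#' scale-free network, and random geometric graphs on the unit square, where
#' two agents are linked when their Euclidean distance is at most `radius`.
#' A geometric topology can be static, or dynamic: agents then perform a
#' correlated random walk and the adjacency is recomputed every timestep.
#'
#' @param kind one of `"complete"`, `"erdos_renyi"`, `"barabasi_albert"`,
#'   `"geometric_static"`, `"geometric_dynamic"`.
#' @param n number of agents.
#' @param p edge probability (Erdos-Renyi).
#' @param m attachment count (Barabasi-Albert).
#' @param radius interaction radius (geometric kinds).
#' @param speed per-step displacement of the correlated random walk
#'   (geometric_dynamic).
#' @param turning_noise standard deviation (radians) of the per-step heading
#'   change (geometric_dynamic).
#' @param seed integer seed for graph/position generation.
#' @return an object of class `interaction_topology`.
#' @examples
#' top <- build_topology("erdos_renyi", n = 50, p = 0.1, seed = 1)
#' @export
build_topology <- function(kind = c("complete", "erdos_renyi",
                                    "barabasi_albert", "geometric_static",
                                    "geometric_dynamic"),
                           n, p = NULL, m = NULL, radius = NULL,
                           speed = 0.01, turning_noise = 0.3, seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  adj <- NULL
  positions <- NULL
  if (kind == "erdos_renyi") {
    if (is.null(p) || p < 0 || p > 1) {
      stop("erdos_renyi requires edge probability p in [0, 1]", call. = FALSE)
    }
    g <- igraph::sample_gnp(n, p)
    adj <- lapply(igraph::as_adj_list(g), function(v) as.integer(v) - 1L)
  } else if (kind == "barabasi_albert") {
    if (is.null(m) || m < 1) {
      stop("barabasi_albert requires attachment count m >= 1", call. = FALSE)
    }
    g <- igraph::sample_pa(n, m = m, directed = FALSE)
    adj <- lapply(igraph::as_adj_list(g), function(v) as.integer(v) - 1L)
  } else if (kind %in% c("geometric_static", "geometric_dynamic")) {
    if (is.null(radius) || radius <= 0) {
      stop("geometric topologies require radius > 0", call. = FALSE)
    }
    positions <- cbind(stats::runif(n), stats::runif(n))
    if (kind == "geometric_static") {
      adj <- lapply(seq_len(n), function(i) {
        d2 <- (positions[, 1] - positions[i, 1])^2 +
          (positions[, 2] - positions[i, 2])^2
        which(d2 <= radius^2 & seq_len(n) != i) - 1L
      })
    }
  }
  structure(list(kind = kind, n = as.integer(n), adj = adj,
                 positions = positions, p = p, m = m, radius = radius,
                 speed = speed, turning_noise = turning_noise, seed = seed),
            class = "interaction_topology")
}

#' Neighbour count per agent
#' @param topology an `interaction_topology`.
#' @return integer vector of degrees (for static kinds).
#' @export
topology_degrees <- function(topology) {
  stopifnot(inherits(topology, "interaction_topology"))
  if (topology$kind == "complete") {
    return(rep(topology$n - 1L, topology$n))
  }
  if (is.null(topology$adj)) {
    stop("degrees of a dynamic topology change every step", call. = FALSE)
  }
  lengths(topology$adj)
}

#' Compile reaction rules to a per-agent probabilistic state machine
#'
#' Each dynamic species becomes an agent state.  Unimolecular rules become
#' spontaneous transitions; bimolecular rules become pairwise interactive
#' transitions in which the two written reactant positions map onto the two
#' written product positions.  Only rules that conserve the number of agents
#' and involve at most two of them are agent-interpretable; reservoir
#' species, species elimination, creation and destruction are rejected.
#'
#' @param model a `reaction_model`.
#' @return an object of class `agent_state_machine` with tibbles
#'   `spontaneous` (from, to, rate) and `interactive` (s1, s2, t1, t2, rate);
#'   rates are symbolic expressions over the model parameters.
#' @examples
#' bees <- load_fixture("honeybee")$model
#' compile_state_machine(bees)
#' @export
compile_state_machine <- function(model) {
  stopifnot(inherits(model, "reaction_model"))
  if (length(model$eliminated) > 0L) {
    stop("agent compilation requires the full model; species eliminated by ",
         "substitution cannot be represented as agents", call. = FALSE)
  }
  dyn <- dynamic_species(model)
  spont <- list()
  inter <- list()
  for (j in seq_along(model$reactions)) {
    rx <- model$reactions[[j]]
    rule <- paste(side_text(rx$lhs, list()), "->", side_text(rx$rhs, list()))
    if (any(!vapply(c(rx$lhs, rx$rhs), function(tm) tm$name %in% dyn, logical(1)))) {
      stop("rule '", rule, "' involves a constant species and is not ",
           "agent-interpretable", call. = FALSE)
    }
    lhs <- unlist(lapply(rx$lhs, function(tm) rep(tm$name, tm$coef)))
    rhs <- unlist(lapply(rx$rhs, function(tm) rep(tm$name, tm$coef)))
    if (length(lhs) != length(rhs)) {
      stop("rule '", rule, "' changes the number of agents and is not ",
           "agent-interpretable", call. = FALSE)
    }
    if (length(lhs) == 1L) {
      spont[[length(spont) + 1L]] <- list(from = lhs[1], to = rhs[1],
                                          rate = rx$rate)
    } else if (length(lhs) == 2L) {
      inter[[length(inter) + 1L]] <- list(s1 = lhs[1], s2 = lhs[2],
                                          t1 = rhs[1], t2 = rhs[2],
                                          rate = rx$rate)
    } else {
      stop("rule '", rule, "' involves more than two agents and is not ",
           "agent-interpretable", call. = FALSE)
    }
  }
  structure(list(
    states = dyn,
    spontaneous = tibble::tibble(
      from = vapply(spont, `[[`, character(1), "from"),
      to = vapply(spont, `[[`, character(1), "to"),
      rate = lapply(spont, `[[`, "rate")),
    interactive = tibble::tibble(
      s1 = vapply(inter, `[[`, character(1), "s1"),
      s2 = vapply(inter, `[[`, character(1), "s2"),
      t1 = vapply(inter, `[[`, character(1), "t1"),
      t2 = vapply(inter, `[[`, character(1), "t2"),
      rate = lapply(inter, `[[`, "rate"))
  ), class = "agent_state_machine")
}

#' @export
print.agent_state_machine <- function(x, ...) {
  cat("<agent_state_machine> states:", paste(x$states, collapse = ", "), "\n")
  cat(nrow(x$spontaneous), "spontaneous transition(s):\n")
  for (i in seq_len(nrow(x$spontaneous))) {
    cat("  ", x$spontaneous$from[i], "->", x$spontaneous$to[i], ":",
        q_deparse(x$spontaneous$rate[[i]]), "\n")
  }
  cat(nrow(x$interactive), "interactive transition(s):\n")
  for (i in seq_len(nrow(x$interactive))) {
    cat("  (", x$interactive$s1[i], ",", x$interactive$s2[i], ") -> (",
        x$interactive$t1[i], ",", x$interactive$t2[i], ") :",
        q_deparse(x$interactive$rate[[i]]), "\n")
  }
  invisible(x)
}

#' Timestep matched to the population-level time scale
#'
#' The synchronous-step agent simulation uses per-step transition
#' probabilities `rate * dt`.  To keep every such probability at or below
#' `safety`, the timestep is `safety / R_max`, where `R_max` is the maximum
#' over agent states of the total outgoing rate (spontaneous plus all
#' interactive rules the state participates in, assuming a matching partner
#' is always available).
#'
#' @param machine an `agent_state_machine`.
#' @param params named list binding the rate parameters.
#' @param safety maximum tolerated per-step probability (0 < safety <= 1).
#' @return the timestep dt.
#' @export
choose_timestep <- function(machine, params, safety = 0.5) {
  stopifnot(inherits(machine, "agent_state_machine"),
            safety > 0, safety <= 1)
  env <- as.list(params)
  rmax <- 0
  for (s in machine$states) {
    r <- 0
    for (i in seq_len(nrow(machine$spontaneous))) {
      if (machine$spontaneous$from[i] == s) {
        r <- r + q_eval(machine$spontaneous$rate[[i]], env)
      }
    }
    for (i in seq_len(nrow(machine$interactive))) {
      if (machine$interactive$s1[i] == s || machine$interactive$s2[i] == s) {
        r <- r + q_eval(machine$interactive$rate[[i]], env)
      }
    }
    rmax <- max(rmax, r)
  }
  if (rmax <= 0) {
    stop("all transition rates are zero; the timestep is undefined", call. = FALSE)
  }
  safety / rmax
}

# orientation-resolved numeric probability tables for the C++ engine.
# For distinct reactant states either agent of a pair may initiate, so each
# orientation carries rate * dt / 2, keeping the expected pairwise event rate
# equal to the SSA propensity on the complete graph; identical-state pairs
# have a single orientation at full rate * dt.
agent_tables <- function(machine, params, dt, safety) {
  env <- as.list(params)
  code <- stats::setNames(seq_along(machine$states) - 1L, machine$states)
  sp <- machine$spontaneous
  spont <- matrix(0, nrow(sp), 3)
  for (i in seq_len(nrow(sp))) {
    pr <- q_eval(sp$rate[[i]], env) * dt
    spont[i, ] <- c(code[[sp$from[i]]], code[[sp$to[i]]], pr)
  }
  iv <- machine$interactive
  rows <- list()
  for (i in seq_len(nrow(iv))) {
    r <- q_eval(iv$rate[[i]], env)
    if (iv$s1[i] == iv$s2[i]) {
      rows[[length(rows) + 1L]] <- c(code[[iv$s1[i]]], code[[iv$s2[i]]],
                                     code[[iv$t1[i]]], code[[iv$t2[i]]],
                                     r * dt)
    } else {
      rows[[length(rows) + 1L]] <- c(code[[iv$s1[i]]], code[[iv$s2[i]]],
                                     code[[iv$t1[i]]], code[[iv$t2[i]]],
                                     r * dt / 2)
      rows[[length(rows) + 1L]] <- c(code[[iv$s2[i]]], code[[iv$s1[i]]],
                                     code[[iv$t2[i]]], code[[iv$t1[i]]],
                                     r * dt / 2)
    }
  }
  inter <- if (length(rows) > 0L) do.call(rbind, rows) else matrix(0, 0, 5)
  if (any(spont[, 3] > safety + 1e-9) || (nrow(inter) > 0L && any(inter[, 5] > safety + 1e-9))) {
    stop("a per-step transition probability exceeds the safety bound; ",
         "decrease dt", call. = FALSE)
  }
  list(spont = spont, inter = inter, code = code)
}

#' Agent-based simulation on an interaction topology
#'
#' Executes the compiled state machine in synchronous discrete timesteps.
#' Each step, agents act in randomised order: an agent fires a spontaneous
#' transition with probability rate * dt, or selects one neighbour uniformly
#' at random and, when the pair matches an interactive rule, fires it with
#' probability rate * dt, updating both agents; an agent that already took
#' part in a transition this step cannot take part again.  On the dynamic
#' geometric topology agents additionally perform a correlated random walk
#' (periodic unit square) and the adjacency is recomputed every step.
#'
#' @param machine an `agent_state_machine`.
#' @param topology an `interaction_topology` (its `n` is the population).
#' @param init named agent counts per state (summing to `n`), or a character
#'   vector of length `n` with one state per agent.
#' @param params named list binding the rate parameters.
#' @param t_max simulated time horizon.
#' @param seed integer seed.
#' @param safety per-step probability bound used when `dt` is chosen
#'   automatically; see [choose_timestep()].
#' @param dt timestep override (default: `choose_timestep(...)`).
#' @param record_positions record per-step agent coordinates
#'   (geometric_dynamic only).
#' @return a tibble of class `agent_trajectory` with column `t` and one count
#'   column per state; attributes `dt` and (optionally) `positions`.
#' @examples
#' bees <- load_fixture("honeybee")
#' sm <- compile_state_machine(bees$model)
#' top <- build_topology("complete", n = 50)
#' tr <- multiagent_trajectory(sm, top, c(U = 50, A = 0, B = 0),
#'                             bees$params$fig6_left, t_max = 5, seed = 1)
#' @export
multiagent_trajectory <- function(machine, topology, init, params, t_max,
                                  seed = NULL, safety = 0.5, dt = NULL,
                                  record_positions = FALSE) {
  stopifnot(inherits(machine, "agent_state_machine"),
            inherits(topology, "interaction_topology"), t_max > 0)
  if (!is.null(seed)) set.seed(seed)
  bound <- if (is.null(dt)) safety else 1
  if (is.null(dt)) dt <- choose_timestep(machine, params, safety)
  tab <- agent_tables(machine, params, dt, safety = bound)
  state0 <- agent_init_states(init, machine$states, topology$n)
  nsteps <- as.integer(ceiling(t_max / dt - 1e-9))
  kind_code <- switch(topology$kind,
                      complete = 0L, geometric_dynamic = 2L, 1L)
  pos0 <- topology$positions
  if (is.null(pos0)) pos0 <- matrix(0, topology$n, 2)
  if (kind_code == 2L && is.null(topology$positions)) {
    pos0 <- cbind(stats::runif(topology$n), stats::runif(topology$n))
  }
  adj <- topology$adj
  if (is.null(adj)) adj <- list()
  res <- .agents_core(
    state0 = tab$code[state0], topo_kind = kind_code, adj = adj,
    pos0 = pos0, radius = if (is.null(topology$radius)) 0 else topology$radius,
    speed = topology$speed, sigma_turn = topology$turning_noise,
    spont = tab$spont, inter = tab$inter,
    nstates = length(machine$states), nsteps = nsteps,
    record_positions = record_positions)
  counts <- res$counts
  colnames(counts) <- machine$states
  out <- tibble::as_tibble(as.data.frame(cbind(t = (0:nsteps) * dt, counts)))
  attr(out, "variables") <- machine$states
  attr(out, "dt") <- dt
  attr(out, "final_state") <- machine$states[res$final_state + 1L]
  if (!is.null(res$positions)) attr(out, "positions") <- res$positions
  class(out) <- c("agent_trajectory", "rxn_trajectory", class(out))
  out
}

agent_init_states <- function(init, states, n) {
  if (is.character(init)) {
    stopifnot(length(init) == n, all(init %in% states))
    return(init)
  }
  init <- resolve_state(init, states)
  if (sum(init) != n) {
    stop("initial counts sum to ", sum(init), " but the topology has ", n,
         " agents", call. = FALSE)
  }
  rep(states, times = as.integer(init))
}

#' Ensemble of agent-based simulations
#'
#' Independent runs with decorrelated sub-seeds; final-state statistics and
#' the ensemble-mean count trajectory (runs share the timestep, so the grids
#' align).
#'
#' @inheritParams multiagent_trajectory
#' @param runs number of independent runs.
#' @param seed master seed.
#' @return an `ensemble_result` (see [ssa_ensemble()]) with `$grid` holding
#'   the ensemble-mean trajectory.
#' @export
multiagent_ensemble <- function(machine, topology, init, params, t_max,
                                runs, seed = 1L, safety = 0.5, dt = NULL) {
  stopifnot(runs >= 1L)
  if (is.null(dt)) dt <- choose_timestep(machine, params, safety)
  finals <- NULL
  gsum <- NULL
  for (r in seq_len(runs)) {
    tr <- multiagent_trajectory(machine, topology, init, params, t_max,
                                seed = sub_seed(seed, r), safety = safety,
                                dt = dt)
    m <- as.matrix(tr[, machine$states, drop = FALSE])
    if (is.null(gsum)) {
      gsum <- m
      finals <- matrix(0, runs, length(machine$states),
                       dimnames = list(NULL, machine$states))
      gtimes <- tr$t
    } else {
      gsum <- gsum + m
    }
    finals[r, ] <- m[nrow(m), ]
  }
  grid <- tibble::as_tibble(as.data.frame(cbind(t = gtimes, gsum / runs)))
  out <- new_ensemble_result(finals, runs, seed, topology$n, t_max, grid,
                             engine = "multiagent")
  out$dt <- dt
  out
}
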