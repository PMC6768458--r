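#' Reaction propensities at a discrete state
#'
#' Propensity of reaction i at population state n:
#' `rate_i * V^(1 - sum(alpha)) * prod_j ((n_j))_alpha_j`, with falling
#' factorials `((n))_a = n! / (n - a)!`.  Constant reservoir species
#' contribute their fixed count `Phi * V`, so unimolecular propensities are
#' `rate * n` (independent of V) and bimolecular ones `rate * n * (n - 1) / V`.
#' Species eliminated via [substitute_model()] contribute the falling
#' factorial of their replacement expression.
#'
#' @param model a `reaction_model`.
#' @param state named non-negative integer vector over the dynamic species.
#' @param params named list of parameter values; constant species require
#'   their proportion `Phi_<name>`.
#' @param V system size.
#' @return numeric vector of propensities, one per reaction.
#' @examples
#' m <- parse_model("X + X -> EMPTY : h")
#' compute_propensities(m, c(X = 5), list(h = 1), V = 10)  # 5 * 4 / 10
#' @export
compute_propensities <- function(model, state, params, V) {
  stopifnot(inherits(model, "reaction_model"))
  dyn <- dynamic_species(model)
  state <- resolve_state(state, dyn)
  if (any(state < 0)) stop("state counts must be non-negative", call. = FALSE)
  env <- c(as.list(params), as.list(state))
  const <- constant_species(model)
  out <- numeric(length(model$reactions))
  for (j in seq_along(model$reactions)) {
    rx <- model$reactions[[j]]
    a <- q_eval(rx$rate, env)
    n_alpha <- 0L
    for (nm in names(rx$reactants)) {
      al <- rx$reactants[[nm]]
      if (nm %in% const) {
        a <- a * env[[paste0("Phi_", nm)]]^al
      } else if (nm %in% names(model$eliminated)) {
        a <- a * falling_factorial(q_eval(model$eliminated[[nm]], env), al)
        n_alpha <- n_alpha + al
      } else {
        a <- a * falling_factorial(state[[nm]], al)
        n_alpha <- n_alpha + al
      }
    }
    out[j] <- max(a * V^(1L - n_alpha), 0)
  }
  out
}

# numeric simulation tables for the C++ fast path
ssa_tables <- function(model, params, V) {
  dyn <- dynamic_species(model)
  const <- constant_species(model)
  env <- as.list(params)
  rates <- vapply(seq_along(model$reactions), function(j) {
    rx <- model$reactions[[j]]
    r <- q_eval(rx$rate, env)
    if (r <= 0) {
      stop("rate of reaction ", j, " is not strictly positive at the given ",
           "parameters", call. = FALSE)
    }
    for (nm in intersect(names(rx$reactants), const)) {
      ph <- env[[paste0("Phi_", nm)]]
      if (is.null(ph)) {
        stop("missing proportion Phi_", nm, " for constant species", call. = FALSE)
      }
      r <- r * ph^rx$reactants[[nm]]
    }
    r
  }, numeric(1))
  alpha <- matrix(0L, length(dyn), length(model$reactions),
                  dimnames = list(dyn, NULL))
  for (j in seq_along(model$reactions)) {
    rx <- model$reactions[[j]]
    for (nm in intersect(names(rx$reactants), dyn)) {
      alpha[nm, j] <- rx$reactants[[nm]]
    }
  }
  list(rates = rates, alpha = alpha, stoich = stoichiometry(model))
}

#' Exact stochastic simulation (Gillespie direct method)
#'
#' Samples one statistically exact trajectory of the master equation:
#' exponentially distributed waiting times with the total propensity as rate,
#' reactions chosen with probability proportional to their propensity.  The
#' run terminates at `t_max` or when the total propensity reaches zero.
#' Given the same seed the trajectory is reproducible.
#'
#' @inheritParams compute_propensities
#' @param init named non-negative integer initial counts of the dynamic
#'   species.
#' @param t_max simulated time horizon.
#' @param seed integer seed (optional; the current RNG state is used when
#'   omitted).
#' @param max_events safety cap on the number of reaction events.
#' @return a tibble of class `ssa_trajectory` with column `t` (jump times,
#'   starting at 0 and ending at `t_max`) and one count column per species.
#' @examples
#' m <- parse_model("(b) -> X : b0\nX -> EMPTY : d")
#' tr <- ssa_trajectory(m, c(X = 0), list(b0 = 2, d = 1, Phi_b = 1),
#'                      V = 10, t_max = 5, seed = 1)
#' @export
ssa_trajectory <- function(model, init, params, V, t_max, seed = NULL,
                           max_events = 5e6) {
  stopifnot(inherits(model, "reaction_model"), t_max > 0)
  if (!is.null(seed)) set.seed(seed)
  dyn <- dynamic_species(model)
  init <- resolve_state(init, dyn)
  if (any(init < 0) || any(init != round(init))) {
    stop("initial counts must be non-negative integers", call. = FALSE)
  }
  res <- run_ssa(model, init, params, V, t_max, max_events, record = TRUE)
  if (res$truncated) {
    warning("SSA stopped after ", max_events, " events at t = ",
            format(res$times[length(res$times)]), call. = FALSE)
  }
  states <- res$states
  colnames(states) <- dyn
  out <- tibble::as_tibble(as.data.frame(cbind(t = res$times, states)))
  attr(out, "variables") <- dyn
  attr(out, "V") <- V
  attr(out, "seed") <- seed
  class(out) <- c("ssa_trajectory", "rxn_trajectory", class(out))
  out
}

run_ssa <- function(model, init, params, V, t_max, max_events, record) {
  if (length(model$eliminated) == 0L) {
    tab <- ssa_tables(model, params, V)
    .ssa_core(as.integer(init), tab$rates, tab$alpha,
              matrix(as.integer(tab$stoich), nrow = nrow(tab$stoich)),
              V, t_max, as.integer(max_events), record)
  } else {
    ssa_r_fallback(model, init, params, V, t_max, max_events, record)
  }
}

# reference R implementation; also the path for species-eliminated models
ssa_r_fallback <- function(model, init, params, V, t_max, max_events, record) {
  S <- stoichiometry(model)
  n <- init
  t <- 0
  times <- 0
  states <- matrix(n, nrow = 1)
  events <- 0L
  truncated <- FALSE
  repeat {
    a <- compute_propensities(model, n, params, V)
    a0 <- sum(a)
    if (a0 <= 0) break
    tau <- stats::rexp(1, a0)
    if (t + tau > t_max) break
    t <- t + tau
    j <- sample.int(length(a), 1L, prob = a)
    n <- n + S[, j]
    events <- events + 1L
    if (record) {
      times <- c(times, t)
      states <- rbind(states, n)
    }
    if (events >= max_events) { truncated <- TRUE; break }
  }
  times <- c(times, if (truncated) t else t_max)
  states <- rbind(states, n)
  list(times = times, states = states, events = events, truncated = truncated)
}

#' Time average of a jump trajectory
#'
#' The state between jumps is constant, so the average over a window is the
#' holding-time-weighted mean of the recorded states.
#'
#' @param traj an `ssa_trajectory`.
#' @param from,to window bounds (defaults: the whole trajectory).
#' @return named numeric vector of per-species time averages.
#' @export
trajectory_time_average <- function(traj, from = NULL, to = NULL) {
  stopifnot(inherits(traj, "ssa_trajectory"))
  vars <- attr(traj, "variables")
  tt <- traj$t
  if (is.null(from)) from <- tt[1]
  if (is.null(to)) to <- tt[length(tt)]
  stopifnot(to > from)
  lo <- pmax(tt, from)
  hi <- pmin(c(tt[-1], to), to)
  w <- pmax(hi - lo, 0)
  sts <- as.matrix(traj[, vars, drop = FALSE])
  stats::setNames(as.numeric(colSums(sts * w) / sum(w)), vars)
}

#' Ensembles of stochastic simulations
#'
#' Runs independent SSA trajectories with decorrelated per-run seeds and
#' aggregates the final-state distribution: per-run final counts, their mean
#' and covariance, per-species histograms, and (optionally) the ensemble-mean
#' trajectory resampled on a regular grid.
#'
#' @inheritParams ssa_trajectory
#' @param runs number of independent trajectories.
#' @param seed integer master seed; run r uses a sub-seed derived from
#'   (seed, r).
#' @param grid_points if > 0, each run is resampled on this many regular time
#'   points and the ensemble mean trajectory is returned in `$grid`.
#' @return an object of class `ensemble_result`.
#' @examples
#' bees <- load_fixture("honeybee")
#' ens <- ssa_ensemble(bees$model, c(U = 50, A = 0, B = 0),
#'                     bees$params$fig6_left, V = 50, t_max = 10,
#'                     runs = 10, seed = 1)
#' ens$mean
#' @export
ssa_ensemble <- function(model, init, params, V, t_max, runs, seed = 1L,
                         grid_points = 0L, max_events = 5e6) {
  stopifnot(runs >= 1L)
  dyn <- dynamic_species(model)
  init <- resolve_state(init, dyn)
  finals <- matrix(0, runs, length(dyn), dimnames = list(NULL, dyn))
  grid <- NULL
  gsum <- NULL
  gtimes <- NULL
  if (grid_points > 0L) {
    gtimes <- seq(0, t_max, length.out = grid_points)
    gsum <- matrix(0, grid_points, length(dyn), dimnames = list(NULL, dyn))
  }
  for (r in seq_len(runs)) {
    set.seed(sub_seed(seed, r))
    res <- run_ssa(model, init, params, V, t_max, max_events,
                   record = grid_points > 0L)
    st <- res$states
    finals[r, ] <- st[nrow(st), ]
    if (grid_points > 0L) {
      for (k in seq_along(dyn)) {
        gsum[, k] <- gsum[, k] + stats::approx(res$times, st[, k],
                                               xout = gtimes,
                                               method = "constant",
                                               rule = 2)$y
      }
    }
  }
  if (grid_points > 0L) {
    grid <- tibble::as_tibble(as.data.frame(cbind(t = gtimes, gsum / runs)))
  }
  new_ensemble_result(finals, runs, seed, V, t_max, grid, engine = "ssa")
}

sub_seed <- function(seed, r) {
  as.integer((as.numeric(seed) * 1000003 + 7919 * r) %% 2147483629)
}

new_ensemble_result <- function(finals, runs, seed, V, t_max, grid, engine) {
  mean_ <- colMeans(finals)
  covar <- if (runs > 1L) stats::cov(finals) else
    matrix(0, ncol(finals), ncol(finals),
           dimnames = list(colnames(finals), colnames(finals)))
  hist_ <- lapply(stats::setNames(colnames(finals), colnames(finals)),
                  function(v) table(finals[, v]))
  structure(list(species = colnames(finals), runs = runs, seed = seed,
                 V = V, t_max = t_max, final_states = finals, mean = mean_,
                 covariance = covar, histogram = hist_, grid = grid,
                 engine = engine),
            class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat("<ensemble_result> ", x$runs, " ", x$engine, " run(s), V = ", x$V,
      ", t_max = ", x$t_max, "\n", sep = "")
  cat("final-state mean:\n"); print(x$mean)
  cat("final-state covariance:\n"); print(x$covariance)
  invisible(x)
}
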