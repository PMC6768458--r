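#' Derive mass-action ordinary differential equations
#'
#' Applies the law of mass action to every reaction: the drift of a dynamic
#' species X is the sum over reactions of (net stoichiometry of X) times the
#' rate times the product of reactant abundances raised to their
#' stoichiometric coefficients.  In `"counts"` form abundances are the raw
#' species-count symbols (constant reservoir species enter through their own
#' fixed count symbol); in `"concentrations"` form abundances are the
#' population-proportion symbols `Phi_<name>`.  Eliminated species are
#' replaced by their substitution expression; in concentration form a
#' conserved-total symbol is identified with the whole population, i.e. the
#' proportions of the remaining species sum to at most one.
#'
#' @param model a `reaction_model`.
#' @param form `"counts"` or `"concentrations"`.
#' @return an object of class `ode_system`: variables, symbolic drift,
#'   symbolic Jacobian, and the free parameters.
#' @examples
#' toy <- load_fixture("toy_birth_annihilation")$model
#' derive_odes(toy, form = "concentrations")
#' @export
derive_odes <- function(model, form = c("counts", "concentrations")) {
  stopifnot(inherits(model, "reaction_model"))
  form <- match.arg(form)
  dyn <- dynamic_species(model)
  fac <- species_factors(model, form)
  vars <- if (form == "counts") dyn else paste0("Phi_", dyn)

  drift <- stats::setNames(rep(list(q_const(0)), length(dyn)), vars)
  S <- stoichiometry(model)
  for (j in seq_along(model$reactions)) {
    rx <- model$reactions[[j]]
    flux <- rx$rate
    for (nm in names(rx$reactants)) {
      flux <- q_mul(flux, q_pow(fac[[nm]], rx$reactants[[nm]]))
    }
    for (i in seq_along(dyn)) {
      if (S[dyn[[i]], j] != 0L) {
        drift[[vars[[i]]]] <- q_add(drift[[vars[[i]]]],
                                    q_mul(q_const(S[dyn[[i]], j]), flux))
      }
    }
  }
  new_ode_system(vars, drift, form)
}

# abundance expression per species name for mass-action fluxes
species_factors <- function(model, form) {
  fac <- list()
  for (i in seq_len(nrow(model$species))) {
    nm <- model$species$name[[i]]
    fac[[nm]] <- if (model$species$constant[[i]] || form == "concentrations") {
      q_sym(paste0("Phi_", nm))
    } else {
      q_sym(nm)
    }
    if (!model$species$constant[[i]] && form == "counts") fac[[nm]] <- q_sym(nm)
  }
  for (nm in names(model$eliminated)) {
    rep <- model$eliminated[[nm]]
    if (form == "concentrations") {
      for (s in intersect(q_vars(rep), model$species$name)) {
        rep <- q_subst_sym(rep, s, q_sym(paste0("Phi_", s)))
      }
      for (s in intersect(q_vars(rep), model$conserved_total)) {
        rep <- q_subst_sym(rep, s, q_const(1))
      }
    }
    fac[[nm]] <- rep
  }
  fac
}

new_ode_system <- function(vars, drift, form) {
  jac <- lapply(vars, function(v) {
    stats::setNames(lapply(vars, function(w) q_diff(drift[[v]], w)), vars)
  })
  names(jac) <- vars
  params <- setdiff(unique(unlist(lapply(drift, q_vars))), vars)
  structure(list(variables = vars, drift = drift, jacobian = jac,
                 form = form, parameters = params),
            class = "ode_system")
}

#' Build an ODE system directly from expressions
#'
#' Mainly useful for analysing normal forms and textbook systems that are not
#' derived from a reaction model, e.g. `ode_system(x = "mu * x - x^3")`.
#'
#' @param ... named drift expressions (strings or unevaluated expressions),
#'   one per state variable.
#' @param form label for the state representation, `"counts"` by default.
#' @return an `ode_system`.
#' @export
ode_system <- function(..., form = "counts") {
  eqs <- list(...)
  stopifnot(length(eqs) > 0L, !is.null(names(eqs)), all(nzchar(names(eqs))))
  drift <- lapply(eqs, function(e) {
    if (is.character(e)) q_parse(e) else q_from_lang(e)
  })
  new_ode_system(names(eqs), drift, form)
}

#' @export
print.ode_system <- function(x, ...) {
  cat("<ode_system> (", x$form, " form)\n", sep = "")
  for (v in x$variables) {
    cat("  d", v, "/dt = ", q_deparse(x$drift[[v]]), "\n", sep = "")
  }
  if (length(x$parameters) > 0L) {
    cat("parameters:", paste(sort(x$parameters), collapse = ", "), "\n")
  }
  invisible(x)
}

# bind parameter values; return numeric drift and Jacobian functions of state
ode_functions <- function(odes, params) {
  params <- as.list(params)
  unbound <- setdiff(odes$parameters, names(params))
  if (length(unbound) > 0L) {
    stop("unbound parameter(s): ", paste(unbound, collapse = ", "), call. = FALSE)
  }
  db <- lapply(odes$drift, q_bind, env = params)
  jb <- lapply(odes$jacobian, function(row) lapply(row, q_bind, env = params))
  vars <- odes$variables
  f <- function(x) {
    env <- as.list(stats::setNames(x, vars))
    vapply(db, q_eval, numeric(1), env = env)
  }
  J <- function(x) {
    env <- as.list(stats::setNames(x, vars))
    matrix(unlist(lapply(jb, function(row) vapply(row, q_eval, numeric(1), env = env))),
           nrow = length(vars), byrow = TRUE, dimnames = list(vars, vars))
  }
  list(f = f, J = J, drift_bound = db)
}

#' Numerically integrate an ODE system
#'
#' Adaptive stiff/non-stiff integration (lsoda) with relative tolerance 1e-8
#' and absolute tolerance 1e-10, sampled on a regular time grid.
#'
#' @param odes an `ode_system`.
#' @param init named numeric initial state (one value per state variable).
#' @param params named list of parameter values; every free parameter must be
#'   bound.
#' @param t_end end time.
#' @param n_points number of output samples (including t = 0).
#' @param output `"counts"` for the state as integrated, or `"proportions"`
#'   to divide each state by the total population at t = 0.
#' @return a tibble of class `rxn_trajectory` with column `t` and one column
#'   per state variable.
#' @examples
#' decay <- ode_system(x = "-x")
#' tr <- integrate_odes(decay, c(x = 1), list(), t_end = 1)
#' tail(tr, 1)  # ~ exp(-1)
#' @export
integrate_odes <- function(odes, init, params = list(), t_end, n_points = 201L,
                           output = c("counts", "proportions")) {
  stopifnot(inherits(odes, "ode_system"), t_end > 0)
  output <- match.arg(output)
  init <- resolve_state(init, odes$variables)
  fns <- ode_functions(odes, params)
  times <- seq(0, t_end, length.out = n_points)
  sol <- deSolve::ode(
    y = init, times = times,
    func = function(t, y, p) list(fns$f(y)),
    parms = NULL, method = "lsoda", rtol = 1e-8, atol = 1e-10
  )
  states <- sol[, -1, drop = FALSE]
  bad <- !apply(is.finite(states), 1, all)
  if (any(bad)) {
    stop("non-finite state encountered at t = ", format(sol[min(which(bad)), 1]),
         call. = FALSE)
  }
  if (nrow(states) < length(times)) {
    stop("integration failed at t = ", format(sol[nrow(sol), 1]), call. = FALSE)
  }
  if (output == "proportions") states <- states / sum(init)
  out <- tibble::as_tibble(as.data.frame(cbind(t = sol[, 1], states)))
  attr(out, "variables") <- odes$variables
  attr(out, "units") <- output
  class(out) <- c("rxn_trajectory", class(out))
  out
}

resolve_state <- function(init, vars) {
  if (is.null(names(init)) || all(!nzchar(names(init)))) {
    stopifnot(length(init) == length(vars))
    names(init) <- vars
  }
  miss <- setdiff(vars, names(init))
  if (length(miss) > 0L) {
    stop("initial state missing variable(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  as.numeric(init[vars]) -> v
  stats::setNames(v, vars)
}

#' Locate and classify fixed points
#'
#' Equilibria of the drift inside a box.  One-dimensional systems whose drift
#' is a polynomial (after binding parameters) are solved exactly via
#' polynomial root enumeration; otherwise a grid of damped-Newton starts is
#' used (8 starts per dimension).  Roots are polished by Newton iteration,
#' merged within an absolute tolerance of 1e-6, and classified from the real
#' parts of the Jacobian eigenvalues with threshold 1e-9; a point with an
#' eigenvalue real part inside the threshold is flagged `marginal` and
#' conservatively classified unstable.
#'
#' @param odes an `ode_system`.
#' @param params named list binding every free parameter.
#' @param lower,upper numeric bounds of the search box (recycled to the
#'   system dimension).
#' @return a tibble of class `rxn_fixed_points`: one row per fixed point with
#'   the state columns, `classification` (stable/unstable/saddle),
#'   `marginal`, and an `eigenvalues` list-column.
#' @examples
#' logistic <- ode_system(x = "x * (1 - x)")
#' find_fixed_points(logistic, list(), lower = -0.5, upper = 1.5)
#' @export
find_fixed_points <- function(odes, params = list(), lower, upper) {
  stopifnot(inherits(odes, "ode_system"))
  vars <- odes$variables
  d <- length(vars)
  lower <- rep_len(lower, d); upper <- rep_len(upper, d)
  stopifnot(all(upper > lower), all(is.finite(lower)), all(is.finite(upper)))
  fns <- ode_functions(odes, params)

  roots <- list()
  db <- fns$drift_bound[[1]]
  if (d == 1L && length(p_vars(db$den)) == 0L) {
    co <- p_unicoeffs(db$num, vars)
    if (length(co) > 1L || any(co != 0)) {
      if (length(co) > 1L) {
        for (z in polyroot(co)) {
          if (abs(Im(z)) < 1e-7 * (1 + abs(Re(z)))) roots <- c(roots, list(Re(z)))
        }
      }
    }
  }
  if (length(roots) == 0L) {
    nstart <- if (d <= 2L) 8L else 4L
    grids <- lapply(seq_len(d), function(i) {
      seq(lower[i], upper[i], length.out = nstart + 2L)[-c(1L, nstart + 2L)]
    })
    starts <- as.matrix(do.call(expand.grid, grids))
    roots <- lapply(seq_len(nrow(starts)), function(i) as.numeric(starts[i, ]))
  }

  tol <- 1e-8
  found <- list()
  for (x0 in roots) {
    x <- newton_root(fns$f, fns$J, as.numeric(x0))
    if (is.null(x)) next
    if (any(x < lower - 1e-7) || any(x > upper + 1e-7)) next
    if (max(abs(fns$f(x))) > tol) next
    dup <- FALSE
    for (y in found) if (max(abs(x - y)) < 1e-6) { dup <- TRUE; break }
    if (!dup) found[[length(found) + 1L]] <- x
  }

  cls <- character(0); marg <- logical(0); eig <- list()
  for (x in found) {
    ev <- eigen(fns$J(x), only.values = TRUE)$values
    re <- Re(ev)
    thr <- 1e-9
    m <- any(abs(re) <= thr)
    k <- if (!m && all(re < -thr)) "stable"
         else if (!m && all(re > thr)) "unstable"
         else if (!m) "saddle"
         else "unstable"
    cls <- c(cls, k); marg <- c(marg, m); eig <- c(eig, list(ev))
  }

  states <- if (length(found) > 0L) do.call(rbind, found) else
    matrix(numeric(0), ncol = d)
  colnames(states) <- vars
  out <- tibble::as_tibble(as.data.frame(states))
  out$classification <- cls
  out$marginal <- marg
  out$eigenvalues <- eig
  attr(out, "variables") <- vars
  class(out) <- c("rxn_fixed_points", class(out))
  out
}

newton_root <- function(f, J, x0, tol = 1e-11, maxit = 100L) {
  x <- x0
  fx <- tryCatch(f(x), error = function(e) NULL)
  if (is.null(fx) || any(!is.finite(fx))) return(NULL)
  for (it in seq_len(maxit)) {
    if (max(abs(fx)) < tol) return(x)
    Jx <- tryCatch(J(x), error = function(e) NULL)
    if (is.null(Jx) || any(!is.finite(Jx))) return(NULL)
    step <- tryCatch(solve(Jx, -fx), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    lambda <- 1
    repeat {
      xn <- x + lambda * step
      fn <- tryCatch(f(xn), error = function(e) NULL)
      ok <- !is.null(fn) && all(is.finite(fn)) &&
        max(abs(fn)) <= (1 - 1e-4 * lambda) * max(abs(fx)) + 1e-14
      if (ok) { x <- xn; fx <- fn; break }
      lambda <- lambda / 2
      if (lambda < 1e-6) return(if (max(abs(fx)) < 1e-8) x else NULL)
    }
  }
  if (max(abs(fx)) < 1e-8) x else NULL
}

#' Sample the phase-plane vector field
#'
#' Evaluates the drift on a regular lattice for one- or two-dimensional
#' systems (the basis of vector and stream phase portraits).  Higher
#' dimensional systems are rejected; reduce them first with
#' [substitute_model()].
#'
#' @inheritParams find_fixed_points
#' @param n lattice nodes per dimension.
#' @param include_fixed_points if `TRUE` the located fixed points in the same
#'   box are attached as attribute `"fixed_points"` (the stream-plot variant).
#' @return a tibble of class `rxn_field` with the state columns, one `d<var>`
#'   column per variable, and `speed`.
#' @export
sample_field <- function(odes, params = list(), lower, upper, n = 10L,
                         include_fixed_points = FALSE) {
  stopifnot(inherits(odes, "ode_system"))
  d <- length(odes$variables)
  if (d > 2L) {
    stop("phase-plane sampling supports 1- or 2-dimensional systems; ",
         "eliminate species with substitute_model() first", call. = FALSE)
  }
  lower <- rep_len(lower, d); upper <- rep_len(upper, d)
  fns <- ode_functions(odes, params)
  grids <- lapply(seq_len(d), function(i) seq(lower[i], upper[i], length.out = n))
  nodes <- as.matrix(do.call(expand.grid, grids))
  colnames(nodes) <- odes$variables
  dv <- t(apply(nodes, 1, fns$f))
  if (d == 1L) dv <- matrix(dv, ncol = 1L)
  colnames(dv) <- paste0("d", odes$variables)
  out <- tibble::as_tibble(as.data.frame(cbind(nodes, dv)))
  out$speed <- sqrt(rowSums(dv^2))
  attr(out, "variables") <- odes$variables
  if (include_fixed_points) {
    attr(out, "fixed_points") <- find_fixed_points(odes, params, lower, upper)
  }
  class(out) <- c("rxn_field", class(out))
  out
}
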