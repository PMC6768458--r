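#' Derive the chemical master equation
#'
#' Builds the continuous-time evolution equation for the probability
#' distribution over discrete population states as a symbolic object.  Each
#' reaction i with reactant coefficients alpha and product coefficients beta
#' contributes one term
#'
#'   rate_i * V^(1 - sum(alpha)) * (prod_k E_k^(alpha_k - beta_k) - 1) *
#'     prod_j ((n_j))_alpha_j * P({n_k}; t)
#'
#' where `E_k^m` is the step operator shifting the count of species k by m
#' inside P, `((n))_a = n! / (n - a)!` is the falling factorial, and V is the
#' system size.  A rule pair written as explicit forward and inverse rules
#' yields the two corresponding terms automatically.  Constant reservoir
#' species enter through their fixed proportion, contributing `Phi * V` in
#' place of a dynamic count; species eliminated via [substitute_model()]
#' contribute the falling factorial of their replacement expression.
#'
#' @param model a `reaction_model`.
#' @return an object of class `master_equation` with one symbolic term per
#'   reaction (rate, step-operator shifts, combinatorial factors, V power).
#' @examples
#' toy <- load_fixture("toy_birth_annihilation")$model
#' derive_master_equation(toy)
#' @export
derive_master_equation <- function(model) {
  stopifnot(inherits(model, "reaction_model"))
  dyn <- dynamic_species(model)
  const <- constant_species(model)
  S <- stoichiometry(model)

  terms <- list()
  for (j in seq_along(model$reactions)) {
    rx <- model$reactions[[j]]
    alphas <- stats::setNames(integer(length(dyn)), dyn)
    for (nm in intersect(names(rx$reactants), dyn)) {
      alphas[[nm]] <- rx$reactants[[nm]]
    }
    shifts <- stats::setNames(integer(length(dyn)), dyn)
    shifts[rownames(S)] <- -S[, j]
    const_phi <- stats::setNames(integer(0), character(0))
    for (nm in intersect(names(rx$reactants), const)) {
      const_phi[[nm]] <- rx$reactants[[nm]]
    }
    elim <- list()
    for (nm in intersect(names(rx$reactants), names(model$eliminated))) {
      elim[[nm]] <- list(alpha = rx$reactants[[nm]],
                         replacement = model$eliminated[[nm]])
    }
    n_alpha <- sum(alphas) + sum(vapply(elim, function(e) e$alpha, integer(1)))
    terms[[j]] <- list(rate = rx$rate, shifts = shifts, alphas = alphas,
                       const_phi = const_phi, elim = elim,
                       vpow = 1L - n_alpha)
  }

  structure(list(species = dyn, terms = terms,
                 conserved_total = model$conserved_total),
            class = "master_equation")
}

# propensity of one master-equation term at a numeric state, from the
# symbolic representation (independent of the simulation fast path)
meq_propensity <- function(meq, term_index, state, params, V) {
  tm <- meq$terms[[term_index]]
  env <- as.list(params)
  env[meq$species] <- as.list(as.numeric(state[meq$species]))
  a <- q_eval(tm$rate, env) * V^tm$vpow
  # a reservoir count is Phi*V; its V^alpha cancels the 1/V^alpha scaling
  for (nm in names(tm$const_phi)) {
    a <- a * env[[paste0("Phi_", nm)]]^tm$const_phi[[nm]]
  }
  for (nm in names(tm$alphas)) {
    al <- tm$alphas[[nm]]
    if (al > 0L) a <- a * falling_factorial(env[[nm]], al)
  }
  for (nm in names(tm$elim)) {
    rep_n <- q_eval(tm$elim[[nm]]$replacement, env)
    a <- a * falling_factorial(rep_n, tm$elim[[nm]]$alpha)
  }
  a
}

falling_factorial <- function(n, a) {
  out <- 1
  for (c in seq_len(a) - 1L) out <- out * (n - c)
  out
}

#' @export
print.master_equation <- function(x, ...) {
  cat("<master_equation> dP({", paste(x$species, collapse = ", "),
      "}; t)/dt =\n", sep = "")
  for (tm in x$terms) {
    ops <- character(0)
    for (nm in names(tm$shifts)) {
      if (tm$shifts[[nm]] != 0L) {
        ops <- c(ops, paste0("E[", nm, "]^", tm$shifts[[nm]]))
      }
    }
    op_txt <- if (length(ops) == 0L) "(1 - 1)" else
      paste0("(", paste(ops, collapse = " * "), " - 1)")
    fac <- character(0)
    for (nm in names(tm$const_phi)) {
      fac <- c(fac, paste0("(Phi_", nm, "*V)^", tm$const_phi[[nm]]))
    }
    for (nm in names(tm$alphas)) {
      al <- tm$alphas[[nm]]
      if (al == 1L) fac <- c(fac, nm)
      if (al > 1L) fac <- c(fac, paste0("((", nm, "))_", al))
    }
    for (nm in names(tm$elim)) {
      e <- tm$elim[[nm]]
      base <- paste0("(", q_deparse(e$replacement), ")")
      fac <- c(fac, if (e$alpha == 1L) base else paste0("((", base, "))_", e$alpha))
    }
    vtxt <- if (tm$vpow == 0L) NULL else paste0("V^", tm$vpow)
    pieces <- c(q_deparse(tm$rate), vtxt, op_txt,
                if (length(fac)) paste0("[", paste(fac, collapse = " * "), "]"))
    cat("  + ", paste(pieces, collapse = " * "), " P\n", sep = "")
  }
  invisible(x)
}
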