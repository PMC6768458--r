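# van Kampen system-size expansion and linear noise approximation.
#
# The expansion substitutes n_k = V*Phi_k + sqrt(V)*eta_k into every
# master-equation term, expands each step operator to second order,
#   E^m = 1 + m V^(-1/2) d/deta + (m^2/2) V^(-1) d^2/deta^2,
# and collects powers of sqrt(V).  The order-V^(1/2) terms reproduce the
# macroscopic mass-action equations for Phi; the order-V^0 terms form a
# Fokker-Planck equation linear in eta, from which the drift matrix A (the
# Jacobian of the macroscopic flow) and the diffusion matrix B are read off.
# Lower orders are discarded (linear noise approximation).

SQRTV <- "sqrtV"

#' van Kampen system-size expansion of a master equation
#'
#' @param meq a `master_equation` from [derive_master_equation()].
#' @return an object of class `linear_noise` with components:
#'   `macroscopic` (an `ode_system` in the `Phi_` proportion variables),
#'   `A` and `B` (symbolic drift and diffusion matrices, as list-matrices of
#'   rational expressions), and `fpe` (the order-V^0 linear Fokker-Planck
#'   operator as a list of terms, each a derivative multi-index in the
#'   `eta_` variables plus a symbolic coefficient).
#' @examples
#' toy <- load_fixture("toy_birth_annihilation")$model
#' lnr <- van_kampen_expand(derive_master_equation(toy))
#' lnr$macroscopic
#' fpe_coefficient(lnr, deriv = c(X = 1), monomial = c(h = 1, Phi_X = 1, eta_X = 1))
#' @export
van_kampen_expand <- function(meq) {
  stopifnot(inherits(meq, "master_equation"))
  sp <- meq$species
  K <- length(sp)
  eta <- paste0("eta_", sp)
  phi <- paste0("Phi_", sp)
  names(eta) <- sp; names(phi) <- sp

  count_of <- function(nm) {
    # n = V*Phi + sqrt(V)*eta
    q_new(p_add(p_mul(p_sym(SQRTV, 2L), p_sym(phi[[nm]])),
                p_mul(p_sym(SQRTV, 1L), p_sym(eta[[nm]]))))
  }

  acc <- list()  # derivative multi-index key -> (dmulti, rxq coefficient)
  add_term <- function(dmulti, coef) {
    key <- paste0("D", mono_key(dmulti))  # prefix: "" is not a valid list key
    if (is.null(acc[[key]])) {
      acc[[key]] <<- list(d = dmulti, coef = coef)
    } else {
      acc[[key]]$coef <<- q_add(acc[[key]]$coef, coef)
    }
  }

  for (tm in meq$terms) {
    # propensity factor w(n) after the substitution, as a Laurent polynomial
    # in sqrtV
    w <- q_mul(tm$rate, q_new(p_sym(SQRTV, 2L * tm$vpow)))
    for (nm in names(tm$const_phi)) {
      w <- q_mul(w, q_pow(q_sym(paste0("Phi_", nm)), tm$const_phi[[nm]]))
    }
    for (nm in names(tm$alphas)) {
      al <- tm$alphas[[nm]]
      if (al > 0L) {
        cn <- count_of(nm)
        for (c in seq_len(al) - 1L) w <- q_mul(w, q_sub(cn, q_const(c)))
      }
    }
    for (nm in names(tm$elim)) {
      rep <- tm$elim[[nm]]$replacement
      for (s in intersect(q_vars(rep), sp)) {
        rep <- q_subst_sym(rep, s, count_of(s))
      }
      for (s in intersect(q_vars(rep), meq$conserved_total)) {
        rep <- q_subst_sym(rep, s, q_new(p_sym(SQRTV, 2L)))
      }
      foreign <- intersect(q_vars(rep), setdiff(meq$species, sp))
      if (length(foreign) > 0L) {
        stop("elimination replacement refers to untracked species: ",
             paste(foreign, collapse = ", "), call. = FALSE)
      }
      for (c in seq_len(tm$elim[[nm]]$alpha) - 1L) {
        w <- q_mul(w, q_sub(rep, q_const(c)))
      }
    }

    # step-operator expansion: sum over derivative multi-indices |r| in 1..2
    ms <- tm$shifts
    active <- names(ms)[ms != 0L]
    op <- list()  # list of (coef numeric, r named int)
    for (k in active) {
      op[[length(op) + 1L]] <- list(
        coef = ms[[k]], r = stats::setNames(1L, eta[[k]]))
      op[[length(op) + 1L]] <- list(
        coef = ms[[k]]^2 / 2, r = stats::setNames(2L, eta[[k]]))
    }
    if (length(active) >= 2L) {
      for (a in seq_along(active)) {
        for (b in seq_along(active)) {
          if (a < b) {
            ka <- active[[a]]; kb <- active[[b]]
            op[[length(op) + 1L]] <- list(
              coef = ms[[ka]] * ms[[kb]],
              r = stats::setNames(c(1L, 1L), c(eta[[ka]], eta[[kb]])))
          }
        }
      }
    }

    for (o in op) {
      pieces <- list(list(coef = w, d = stats::setNames(integer(0), character(0))))
      for (s in rep(names(o$r), o$r)) pieces <- apply_eta_deriv(pieces, s)
      pref <- q_new(p_scale(p_sym(SQRTV, -sum(o$r)), o$coef))
      for (pc in pieces) add_term(pc$d, q_mul(pref, pc$coef))
    }
  }

  # split by sqrtV order
  drift <- stats::setNames(rep(list(q_const(0)), K), phi)
  fpe <- list()
  for (key in names(acc)) {
    co <- acc[[key]]$coef
    dmulti <- acc[[key]]$d
    if (length(p_vars(co$den)) > 0L && SQRTV %in% p_vars(co$den)) {
      stop("internal: system-size symbol in a denominator", call. = FALSE)
    }
    maxpow <- p_degree(co$num, SQRTV)
    if (is.finite(maxpow) && maxpow > 1L) {
      stop("internal: expansion produced terms of order above sqrt(V)", call. = FALSE)
    }
    # order sqrt(V): macroscopic flow (coefficient of eta-derivative terms)
    c1 <- p_component(co$num, SQRTV, 1L)
    if (length(c1) > 0L) {
      if (sum(dmulti) != 1L) {
        stop("internal: order-sqrt(V) term with derivative order != 1", call. = FALSE)
      }
      if (any(p_vars(c1) %in% eta)) {
        stop("internal: order-sqrt(V) coefficient depends on eta", call. = FALSE)
      }
      k <- names(dmulti)[dmulti == 1L]
      v <- phi[[match(k, eta)]]
      drift[[v]] <- q_add(drift[[v]], q_neg(q_new(c1, co$den)))
    }
    c0 <- p_component(co$num, SQRTV, 0L)
    if (length(c0) > 0L) {
      fpe[[length(fpe) + 1L]] <- list(deriv = dmulti, coef = q_new(c0, co$den))
    }
  }

  macro <- new_ode_system(unname(phi), drift, "concentrations")

  # read off A (terms eta_j * dP/deta_i) and B (second-derivative terms)
  A <- B <- matrix(list(q_const(0)), K, K, dimnames = list(sp, sp))
  for (term in fpe) {
    dm <- term$deriv
    if (sum(dm) == 1L) {
      i <- match(names(dm)[dm == 1L], eta)
      num <- term$coef$num
      deg <- vapply(eta, function(e) p_degree(num, e), numeric(1))
      if (any(is.finite(deg) & deg > 1L)) {
        stop("internal: first-derivative coefficient not linear in eta", call. = FALSE)
      }
      for (j in seq_len(K)) {
        cj <- p_component_multi(num, eta, stats::setNames(1L, eta[[j]]))
        if (length(cj) > 0L) {
          A[[i, j]] <- q_sub(A[[i, j]], q_new(cj, term$coef$den))
        }
      }
    } else if (sum(dm) == 2L) {
      idx <- match(names(dm), eta)
      if (length(idx) == 1L) {
        B[[idx, idx]] <- q_add(B[[idx, idx]], q_mul(q_const(2), term$coef))
      } else {
        B[[idx[1], idx[2]]] <- q_add(B[[idx[1], idx[2]]], term$coef)
        B[[idx[2], idx[1]]] <- q_add(B[[idx[2], idx[1]]], term$coef)
      }
    }
  }

  structure(list(species = sp, phi = unname(phi), eta = unname(eta),
                 macroscopic = macro, A = A, B = B, fpe = fpe),
            class = "linear_noise")
}

# product-rule application of d/d(eta_sym) to a list of (coef, d) pairs,
# each standing for coef * D^d P
apply_eta_deriv <- function(pieces, sym) {
  out <- list()
  for (pc in pieces) {
    dc <- q_diff(pc$coef, sym)
    if (!q_is_zero(dc)) out[[length(out) + 1L]] <- list(coef = dc, d = pc$d)
    d2 <- pc$d
    d2[sym] <- if (sym %in% names(d2)) d2[[sym]] + 1L else 1L
    out[[length(out) + 1L]] <- list(coef = pc$coef, d = d2)
  }
  out
}

# coefficient of a specific eta-monomial: all eta symbols must match `want`
# exactly (absent means power 0); eta symbols are removed from the result
p_component_multi <- function(p, eta_syms, want) {
  out <- p
  for (e in eta_syms) {
    pw <- if (e %in% names(want)) want[[e]] else 0L
    out <- p_component(out, e, pw)
    if (length(out) == 0L) return(out)
  }
  out
}

#' Extract a numeric coefficient from the linear Fokker-Planck operator
#'
#' Reads off the number multiplying a given monomial inside the coefficient of
#' a given derivative term of the order-V^0 (linear noise) Fokker-Planck
#' equation.  For example `deriv = c(X = 1)` with
#' `monomial = c(h = 1, Phi_X = 1, eta_X = 1)` asks for the coefficient of
#' `Phi_X * eta_X * h * dP/deta_X`.
#'
#' @param lnr a `linear_noise` object.
#' @param deriv named integer vector of derivative orders per species
#'   (`c(X = 2)` means the second eta_X derivative); `NULL` or empty selects
#'   the underived `P` term.
#' @param monomial named integer vector of symbol powers identifying the
#'   monomial (symbols as they appear in the coefficient: parameters,
#'   `Phi_*`, `eta_*`).
#' @return the numeric coefficient (0 when absent).
#' @export
fpe_coefficient <- function(lnr, deriv = NULL, monomial) {
  stopifnot(inherits(lnr, "linear_noise"))
  dm <- stats::setNames(integer(0), character(0))
  if (!is.null(deriv) && length(deriv) > 0L) {
    nm <- paste0("eta_", names(deriv))
    dm <- stats::setNames(as.integer(deriv), nm)
  }
  key <- mono_key(dm)
  total <- p_zero()
  for (term in lnr$fpe) {
    if (mono_key(term$deriv) == key) {
      if (!q_den_is_one(term$coef)) {
        stop("coefficient is not polynomial; extract it manually", call. = FALSE)
      }
      total <- p_add(total, term$coef$num)
    }
  }
  want <- mono_key(stats::setNames(as.integer(monomial), names(monomial)))
  if (want %in% names(total)) unname(total[[want]]) else 0
}

#' @export
print.linear_noise <- function(x, ...) {
  K <- length(x$species)
  cat("<linear_noise> species:", paste(x$species, collapse = ", "), "\n")
  cat("macroscopic equations:\n")
  for (v in x$phi) cat("  d", v, "/dt = ", q_deparse(x$macroscopic$drift[[v]]),
                       "\n", sep = "")
  cat("drift matrix A:\n")
  for (i in seq_len(K)) {
    cat(" ", paste(vapply(seq_len(K), function(j) q_deparse(x$A[[i, j]]),
                          character(1)), collapse = " | "), "\n")
  }
  cat("diffusion matrix B:\n")
  for (i in seq_len(K)) {
    cat(" ", paste(vapply(seq_len(K), function(j) q_deparse(x$B[[i, j]]),
                          character(1)), collapse = " | "), "\n")
  }
  invisible(x)
}

#' Equations of motion for fluctuation moments
#'
#' Integrates the linear Fokker-Planck equation against eta and eta*eta' to
#' obtain the ODEs for the first moments and the distinct second moments of
#' the fluctuation variables.  In matrix form these are d<eta>/dt = A <eta>
#' and dC/dt = A C + C A' + B.
#'
#' @param lnr a `linear_noise` object.
#' @return an object of class `moment_system`: for each moment, a named list
#'   of symbolic coefficients over the moment terms (the name `"1"` holds the
#'   constant, i.e. diffusion, contribution).
#' @export
moment_equations <- function(lnr) {
  stopifnot(inherits(lnr, "linear_noise"))
  sp <- lnr$species
  eta <- lnr$eta
  K <- length(sp)

  targets <- list()
  for (i in seq_len(K)) {
    targets[[moment_label(eta[i])]] <- q_sym(eta[i])
  }
  for (i in seq_len(K)) for (j in i:K) {
    targets[[moment_label(eta[i], eta[j])]] <- q_mul(q_sym(eta[i]), q_sym(eta[j]))
  }

  out <- list()
  for (lab in names(targets)) {
    tgt <- targets[[lab]]
    rhs <- q_const(0)
    for (term in lnr$fpe) {
      g <- q_mul(tgt, term$coef)
      for (s in rep(names(term$deriv), term$deriv)) g <- q_diff(g, s)
      sgn <- if (sum(term$deriv) %% 2L == 0L) 1 else -1
      rhs <- q_add(rhs, q_mul(q_const(sgn), g))
    }
    # expand the eta-polynomial rhs into moment terms
    num <- rhs$num
    terms <- list()
    grab <- function(label, want) {
      cf <- p_component_multi(num, eta, want)
      if (length(cf) > 0L) terms[[label]] <<- q_new(cf, rhs$den)
    }
    grab("1", stats::setNames(integer(0), character(0)))
    for (i in seq_len(K)) grab(moment_label(eta[i]), stats::setNames(1L, eta[i]))
    for (i in seq_len(K)) for (j in i:K) {
      want <- if (i == j) stats::setNames(2L, eta[i]) else
        stats::setNames(c(1L, 1L), c(eta[i], eta[j]))
      grab(moment_label(eta[i], eta[j]), want)
    }
    out[[lab]] <- terms
  }

  structure(list(species = sp, eta = eta, moments = out,
                 first = names(targets)[seq_len(K)],
                 second = names(targets)[-seq_len(K)]),
            class = "moment_system")
}

moment_label <- function(a, b = NULL) {
  if (is.null(b)) paste0("<", a, ">") else paste0("<", a, " ", b, ">")
}

#' @export
print.moment_system <- function(x, ...) {
  for (lab in names(x$moments)) {
    terms <- x$moments[[lab]]
    txt <- vapply(names(terms), function(nm) {
      cf <- q_deparse(terms[[nm]])
      if (nm == "1") cf else paste0("(", cf, ") * ", nm)
    }, character(1))
    cat("d", lab, "/dt = ", paste(txt, collapse = " + "), "\n", sep = "")
  }
  invisible(x)
}

# evaluate the symbolic A and B matrices at numeric Phi / parameter values
lna_matrices <- function(lnr, env) {
  K <- length(lnr$species)
  A <- B <- matrix(0, K, K, dimnames = list(lnr$species, lnr$species))
  for (i in seq_len(K)) for (j in seq_len(K)) {
    A[i, j] <- q_eval(lnr$A[[i, j]], env)
    B[i, j] <- q_eval(lnr$B[[i, j]], env)
  }
  list(A = A, B = B)
}

#' Stationary fluctuation covariance at a stable fixed point
#'
#' Solves the Lyapunov equation A C + C A' + B = 0 with A and B evaluated at
#' a stable fixed point of the macroscopic flow.  The covariance describes
#' the stationary Gaussian fluctuations of the eta variables; on the count
#' scale the standard deviation of n is sqrt(V * diag(C)).  A closed-form
#' (symbolic) solution is attempted for systems of dimension <= 2, with
#' numeric solving as the general path.
#'
#' @param lnr a `linear_noise` object.
#' @param fixed_point named numeric vector giving the fixed point on the
#'   proportion scale; names may be species names or their `Phi_` symbols.
#' @param params named list binding the model parameters (including `Phi_`
#'   values of constant species).
#' @return an object of class `covariance_result`: numeric matrices `A`,
#'   `B`, `C`, the 1-sigma covariance ellipse (principal axes of C), the
#'   projections of the noise onto the eigenvectors of A, and the symbolic
#'   covariance when available.
#' @examples
#' toy <- load_fixture("toy_birth_annihilation")$model
#' lnr <- van_kampen_expand(derive_master_equation(toy))
#' stationary_covariance(lnr, c(X = 1 / sqrt(2)),
#'                       params = list(k = 1, h = 1, Phi_A = 1))
#' @export
stationary_covariance <- function(lnr, fixed_point, params = list()) {
  stopifnot(inherits(lnr, "linear_noise"))
  fp <- normalise_phi(fixed_point, lnr$species)
  env <- c(as.list(params), as.list(fp))
  mats <- lna_matrices(lnr, env)
  A <- mats$A; B <- mats$B
  K <- nrow(A)
  ev <- eigen(A)
  if (any(Re(ev$values) >= 0)) {
    stop("fixed point is not stable (Re(lambda) >= 0); ",
         "no stationary noise exists there", call. = FALSE)
  }
  # vec(AC + CA') = (I x A + A x I) vec(C)
  M <- kronecker(diag(K), A) + kronecker(A, diag(K))
  C <- matrix(solve(M, -as.numeric(B)), K, K)
  C <- (C + t(C)) / 2
  dimnames(C) <- dimnames(A)
  resid <- max(abs(A %*% C + C %*% t(A) + B))

  symb <- tryCatch(
    if (K <= 2L) lyapunov_symbolic(lnr) else NULL,
    error = function(e) NULL)

  ec <- eigen(C, symmetric = TRUE)
  ellipse <- list(center = fp, radii = sqrt(pmax(ec$values, 0)),
                  axes = ec$vectors)
  projections <- NULL
  if (all(abs(Im(ev$vectors)) < 1e-12)) {
    vv <- Re(ev$vectors)
    vv <- sweep(vv, 2, sqrt(colSums(vv^2)), "/")
    projections <- list(directions = vv,
                        sigma = sqrt(pmax(diag(t(vv) %*% C %*% vv), 0)))
  }

  structure(list(species = lnr$species, A = A, B = B, C = C,
                 fixed_point = fp, eigenvalues = ev$values,
                 ellipse = ellipse, projections = projections,
                 symbolic_C = symb, lyapunov_residual = resid),
            class = "covariance_result")
}

normalise_phi <- function(fixed_point, species) {
  nm <- names(fixed_point)
  if (is.null(nm)) {
    stopifnot(length(fixed_point) == length(species))
    nm <- paste0("Phi_", species)
  }
  nm <- ifelse(grepl("^Phi_", nm), nm, paste0("Phi_", nm))
  stats::setNames(as.numeric(fixed_point), nm)
}

# closed-form Lyapunov solution for K <= 2 by symbolic linear elimination
lyapunov_symbolic <- function(lnr) {
  K <- length(lnr$species)
  A <- lnr$A; B <- lnr$B
  if (K == 1L) {
    C <- q_neg(q_div(B[[1, 1]], q_mul(q_const(2), A[[1, 1]])))
    return(matrix(list(C), 1, 1, dimnames = list(lnr$species, lnr$species)))
  }
  # unknowns c11, c12, c22
  idx <- list(c(1L, 1L), c(1L, 2L), c(2L, 2L))
  coef <- matrix(list(q_const(0)), 3, 3)
  rhs <- vector("list", 3)
  getC <- function(i, j, u) {
    # position of C[i,j] among the unknowns
    ii <- min(i, j); jj <- max(i, j)
    which(vapply(idx, function(p) p[1] == ii && p[2] == jj, logical(1)))
  }
  for (e in 1:3) {
    i <- idx[[e]][1]; j <- idx[[e]][2]
    for (k in 1:2) {
      u <- getC(k, j); coef[[e, u]] <- q_add(coef[[e, u]], A[[i, k]])
      u <- getC(i, k); coef[[e, u]] <- q_add(coef[[e, u]], A[[j, k]])
    }
    rhs[[e]] <- q_neg(B[[i, j]])
  }
  sol <- solve_rxq_linear(coef, rhs)
  C <- matrix(list(), 2, 2, dimnames = list(lnr$species, lnr$species))
  C[[1, 1]] <- sol[[1]]; C[[1, 2]] <- sol[[2]]
  C[[2, 1]] <- sol[[2]]; C[[2, 2]] <- sol[[3]]
  C
}

solve_rxq_linear <- function(coef, rhs) {
  n <- length(rhs)
  for (col in seq_len(n)) {
    piv <- NULL
    for (row in col:n) {
      if (!q_is_zero(coef[[row, col]])) { piv <- row; break }
    }
    if (is.null(piv)) stop("singular symbolic system", call. = FALSE)
    if (piv != col) {
      tmp <- coef[col, ]; coef[col, ] <- coef[piv, ]; coef[piv, ] <- tmp
      tmp <- rhs[[col]]; rhs[[col]] <- rhs[[piv]]; rhs[[piv]] <- tmp
    }
    p <- coef[[col, col]]
    for (row in seq_len(n)) {
      if (row != col && !q_is_zero(coef[[row, col]])) {
        f <- q_div(coef[[row, col]], p)
        for (cc in seq_len(n)) {
          coef[[row, cc]] <- q_sub(coef[[row, cc]], q_mul(f, coef[[col, cc]]))
        }
        rhs[[row]] <- q_sub(rhs[[row]], q_mul(f, rhs[[col]]))
      }
    }
  }
  lapply(seq_len(n), function(i) q_div(rhs[[i]], coef[[i, i]]))
}

#' Noise autocorrelation at a stable fixed point
#'
#' The stationary fluctuation process is Ornstein-Uhlenbeck, so the lagged
#' covariance is `<eta(t + tau) eta(t)'> = expm(A * tau) %*% C`.
#'
#' @param cov a `covariance_result`.
#' @param lags non-negative lag times.
#' @return a tibble with columns `lag`, `var_i`, `var_j`, `correlation`.
#' @export
noise_correlation <- function(cov, lags) {
  stopifnot(inherits(cov, "covariance_result"))
  if (any(lags < 0)) stop("lags must be non-negative", call. = FALSE)
  sp <- cov$species
  rows <- list()
  for (tau in lags) {
    Mt <- as.matrix(Matrix::expm(cov$A * tau)) %*% cov$C
    for (i in seq_along(sp)) for (j in seq_along(sp)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        lag = tau, var_i = sp[i], var_j = sp[j], correlation = Mt[i, j])
    }
  }
  dplyr::bind_rows(rows)
}

#' @export
print.covariance_result <- function(x, ...) {
  cat("<covariance_result> stationary fluctuation covariance\n")
  cat("fixed point:", paste(names(x$fixed_point), "=",
                            format(x$fixed_point, digits = 6)), "\n")
  cat("C:\n"); print(x$C)
  cat("1-sigma ellipse radii:", format(x$ellipse$radii, digits = 6), "\n")
  cat("Lyapunov residual:", format(x$lyapunov_residual, digits = 3), "\n")
  invisible(x)
}
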