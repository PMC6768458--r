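# One-parameter equilibrium continuation with pseudo-arclength predictor-
# corrector steps, per-point stability, and detection of limit points (LP,
# fold test function = parameter component of the tangent) and branch points
# (BP, sign change of det(J) without a fold).  Implemented natively: adaptive
# step halving on corrector failure, special-point refinement by bisection in
# arclength.

# numeric residual/Jacobian closures with all parameters but `param` bound
cont_functions <- function(odes, param, params) {
  params <- as.list(params)
  other <- setdiff(odes$parameters, param)
  unbound <- setdiff(other, names(params))
  if (length(unbound) > 0L) {
    stop("unbound parameter(s): ", paste(unbound, collapse = ", "), call. = FALSE)
  }
  pb <- params[other]
  db <- lapply(odes$drift, q_bind, env = pb)
  jb <- lapply(odes$jacobian, function(row) lapply(row, q_bind, env = pb))
  fp <- lapply(odes$drift, function(dr) q_bind(q_diff(dr, param), env = pb))
  vars <- odes$variables
  env_of <- function(x, p) {
    e <- as.list(stats::setNames(x, vars))
    e[[param]] <- p
    e
  }
  list(
    vars = vars,
    f = function(x, p) vapply(db, q_eval, numeric(1), env = env_of(x, p)),
    Jx = function(x, p) {
      e <- env_of(x, p)
      matrix(unlist(lapply(jb, function(row)
        vapply(row, q_eval, numeric(1), env = e))),
        nrow = length(vars), byrow = TRUE)
    },
    Fp = function(x, p) vapply(fp, q_eval, numeric(1), env = env_of(x, p))
  )
}

# unit tangent of the equilibrium curve: null vector of [Jx | Fp]
cont_tangent <- function(fns, x, p, orient = NULL) {
  M <- cbind(fns$Jx(x, p), fns$Fp(x, p))
  v <- svd(M, nu = 0, nv = ncol(M))$v
  tau <- v[, ncol(v)]
  tau <- tau / sqrt(sum(tau^2))
  if (!is.null(orient) && sum(tau * orient) < 0) tau <- -tau
  tau
}

# corrector: Newton on [F(u); tau . (u - target)] with fixed tangent
cont_correct <- function(fns, u, tau, target, tol = 1e-10, maxit = 20L) {
  d <- length(u) - 1L
  for (it in seq_len(maxit)) {
    x <- u[seq_len(d)]; p <- u[d + 1L]
    Fv <- fns$f(x, p)
    g <- sum(tau * (u - target))
    if (max(abs(c(Fv, g))) < tol) return(u)
    M <- rbind(cbind(fns$Jx(x, p), fns$Fp(x, p)), tau)
    step <- tryCatch(solve(M, -c(Fv, g)), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    u <- u + step
    if (any(!is.finite(u))) return(NULL)
  }
  x <- u[seq_len(d)]; p <- u[d + 1L]
  if (max(abs(fns$f(x, p))) < 1e-8) u else NULL
}

point_info <- function(fns, u) {
  d <- length(u) - 1L
  J <- fns$Jx(u[seq_len(d)], u[d + 1L])
  ev <- eigen(J, only.values = TRUE)$values
  list(det = det(J), stable = all(Re(ev) < -1e-9), eig = ev)
}

#' Continue a branch of equilibria in one parameter
#'
#' Pseudo-arclength continuation of the equilibrium curve through a starting
#' point, swept across a parameter range in both directions.  Each accepted
#' point satisfies the drift to 1e-8 after Newton refinement and carries a
#' stability flag.  A limit point (LP) is flagged where the parameter
#' component of the branch tangent changes sign (a fold); a branch point (BP)
#' where det(J) changes sign without a fold.  Special points are refined by
#' bisection to 1e-6 in the parameter.
#'
#' @param odes an `ode_system` of dimension 1 or 2.
#' @param param name of the bifurcation parameter.
#' @param params named list binding the remaining parameters.
#' @param start_state numeric state near an equilibrium at `start_value`
#'   (it is refined; if refinement fails the system is integrated forward and
#'   the final state is used as the start).
#' @param start_value starting parameter value.
#' @param range length-2 numeric: parameter interval to sweep.
#' @param step initial arclength step (default: 1/100 of the range width).
#' @param max_steps cap on continuation steps per direction.
#' @return a tibble of class `rxn_branch` with columns `param` (the
#'   bifurcation parameter value), the state variables, and `stable`;
#'   attribute `"special_points"` holds a tibble of LP/BP locations.
#' @examples
#' fold <- ode_system(x = "mu + x^2")
#' br <- continue_branch(fold, "mu", list(), start_state = c(x = -1),
#'                       start_value = -1, range = c(-2, 0.5))
#' attr(br, "special_points")
#' @export
continue_branch <- function(odes, param, params, start_state, start_value,
                            range, step = NULL, max_steps = 2000L,
                            state_bounds = NULL) {
  stopifnot(inherits(odes, "ode_system"))
  d <- length(odes$variables)
  if (d > 2L) {
    stop("continuation supports systems of dimension <= 2; reduce with ",
         "substitute_model()", call. = FALSE)
  }
  range <- sort(as.numeric(range))
  width <- range[2] - range[1]
  if (is.null(step)) step <- width / 100
  fns <- cont_functions(odes, param, params)

  x0 <- resolve_state(start_state, odes$variables)
  x0 <- newton_root(function(x) fns$f(x, start_value),
                    function(x) fns$Jx(x, start_value), as.numeric(x0))
  if (is.null(x0)) {
    # fall back: integrate from the starting state and use the final state
    pb <- as.list(params); pb[[param]] <- start_value
    tr <- integrate_odes(odes, start_state, pb, t_end = 100, n_points = 11L)
    xT <- as.numeric(tr[nrow(tr), odes$variables])
    x0 <- newton_root(function(x) fns$f(x, start_value),
                      function(x) fns$Jx(x, start_value), xT)
    if (is.null(x0)) {
      stop("no equilibrium found at ", param, " = ", start_value, call. = FALSE)
    }
  }
  u0 <- c(x0, start_value)

  sweep_dir <- function(orient_p) {
    tau <- cont_tangent(fns, x0, start_value,
                        orient = c(rep(0, d), orient_p))
    trace_branch(fns, u0, tau, range, step, max_steps, state_bounds)
  }
  fwd <- sweep_dir(+1)
  bwd <- sweep_dir(-1)
  pts <- rbind(bwd$points[rev(seq_len(nrow(bwd$points))), , drop = FALSE],
               fwd$points[-1, , drop = FALSE])
  specials <- rbind(bwd$specials, fwd$specials)
  assemble_branch(odes, param, pts, specials, params, state_bounds)
}

# core sweep in one orientation; returns accepted points and special points
trace_branch <- function(fns, u0, tau, range, step, max_steps,
                         state_bounds = NULL) {
  d <- length(u0) - 1L
  h <- step
  hmax <- step * 5
  hmin <- step * 1e-6
  info <- point_info(fns, u0)
  pts <- matrix(c(u0, info$stable), nrow = 1)
  specials <- list()
  prev <- list(u = u0, tau = tau, det = info$det, stable = info$stable)
  for (k in seq_len(max_steps)) {
    u1 <- prev$u + h * prev$tau
    u <- cont_correct(fns, u1, prev$tau, u1)
    # reject steps that wander far from the predictor or turn sharply:
    # both are symptoms of jumping onto a different equilibrium sheet
    ok <- !is.null(u) && sqrt(sum((u - prev$u)^2)) <= 3 * h
    if (ok) {
      tau <- cont_tangent(fns, u[seq_len(d)], u[d + 1L], orient = prev$tau)
      ok <- sum(tau * prev$tau) > 0.5 || h <= hmin * 16
    }
    if (!ok) {
      h <- h / 2
      if (h < hmin) break
      next
    }
    info <- point_info(fns, u)
    # special-point tests between prev and current
    fold <- prev$tau[d + 1L] * tau[d + 1L] < 0
    detflip <- prev$det * info$det < 0
    if (fold || detflip) {
      kind <- if (fold) "LP" else "BP"
      ref <- refine_special(fns, prev$u, u, kind)
      if (!is.null(ref)) {
        specials[[length(specials) + 1L]] <- c(ref, kind = kind)
      }
    }
    pts <- rbind(pts, c(u, info$stable))
    prev <- list(u = u, tau = tau, det = info$det, stable = info$stable)
    if (u[d + 1L] < range[1] - 1e-9 || u[d + 1L] > range[2] + 1e-9) break
    x <- u[seq_len(d)]
    if (max(abs(x)) > 1e6) break
    if (!is.null(state_bounds) &&
        (any(x < state_bounds$lower) || any(x > state_bounds$upper))) break
    h <- min(h * 1.3, hmax)
  }
  list(points = pts,
       specials = if (length(specials) > 0L)
         do.call(rbind, lapply(specials, function(s)
           as.data.frame(as.list(s), stringsAsFactors = FALSE)))
       else NULL)
}

# bisection in arclength between two corrected points bracketing a sign
# change of the test function (tangent parameter component for LP, det(J)
# for BP); refined to 1e-6 in the parameter
refine_special <- function(fns, ua, ub, kind) {
  d <- length(ua) - 1L
  testfun <- function(u, tau_ref) {
    if (kind == "BP") return(point_info(fns, u)$det)
    cont_tangent(fns, u[seq_len(d)], u[d + 1L], orient = tau_ref)[d + 1L]
  }
  sec <- (ub - ua); sec <- sec / sqrt(sum(sec^2))
  ga <- testfun(ua, sec); gb <- testfun(ub, sec)
  if (is.na(ga) || is.na(gb) || ga * gb > 0) {
    # endpoints may already have passed the fold; accept midpoint estimate
    mid <- (ua + ub) / 2
    u <- cont_correct(fns, mid, sec, mid)
    if (is.null(u)) return(NULL)
    return(u_record(u, d))
  }
  for (i in 1:60) {
    mid <- (ua + ub) / 2
    u <- cont_correct(fns, mid, sec, mid)
    if (is.null(u)) return(NULL)
    gm <- testfun(u, sec)
    if (ga * gm <= 0) { ub <- u; gb <- gm } else { ua <- u; ga <- gm }
    if (abs(ub[d + 1L] - ua[d + 1L]) < 1e-6 &&
        sqrt(sum((ub - ua)^2)) < 1e-6) break
  }
  u_record((ua + ub) / 2, d)
}

u_record <- function(u, d) {
  out <- as.list(u)
  names(out) <- c(paste0("x", seq_len(d)), "param")
  unlist(out)
}

assemble_branch <- function(odes, param, pts, specials, params,
                            state_bounds = NULL) {
  d <- length(odes$variables)
  df <- as.data.frame(pts)
  names(df) <- c(odes$variables, "param", "stable")
  df$stable <- df$stable > 0.5
  df <- df[df$param >= -Inf, c("param", odes$variables, "stable")]
  out <- tibble::as_tibble(df)
  sp <- if (!is.null(specials) && nrow(specials) > 0L) {
    s <- specials
    names(s)[seq_len(d)] <- odes$variables
    s$param <- as.numeric(s$param)
    for (v in odes$variables) s[[v]] <- as.numeric(s[[v]])
    tibble::as_tibble(s[, c("kind", "param", odes$variables)])
  } else {
    tibble::tibble(kind = character(0), param = numeric(0))
  }
  attr(out, "special_points") <- sp
  attr(out, "param") <- param
  attr(out, "odes") <- odes
  attr(out, "params") <- params
  attr(out, "state_bounds") <- state_bounds
  class(out) <- c("rxn_branch", class(out))
  out
}

#' Follow the bifurcating branch through a branch point
#'
#' At a BP the equilibrium curve crosses another branch.  The curve tangent
#' space there is (numerically) two-dimensional; the second null direction of
#' the extended Jacobian seeds a new continuation, attempted in both
#' orientations.
#'
#' @param branch an `rxn_branch` containing a BP among its special points.
#' @param which index of the special point to switch at (among the BPs).
#' @return an `rxn_branch` for the bifurcating branch.
#' @export
switch_branch <- function(branch, which = 1L) {
  stopifnot(inherits(branch, "rxn_branch"))
  sp <- attr(branch, "special_points")
  bps <- sp[sp$kind == "BP", , drop = FALSE]
  if (nrow(bps) < which) {
    stop("branch has no branch point (BP) to switch at; limit points do not ",
         "carry a second branch", call. = FALSE)
  }
  odes <- attr(branch, "odes")
  param <- attr(branch, "param")
  params <- attr(branch, "params")
  d <- length(odes$variables)
  fns <- cont_functions(odes, param, params)
  xbp <- as.numeric(bps[which, odes$variables])
  pbp <- bps$param[[which]]

  M <- cbind(fns$Jx(xbp, pbp), fns$Fp(xbp, pbp))
  sv <- svd(M, nu = 0, nv = ncol(M))
  # two smallest right-singular vectors span the crossing tangents
  v1 <- sv$v[, ncol(sv$v)]
  v2 <- sv$v[, ncol(sv$v) - 1L]
  # tangent of the current branch at the BP, to project away
  i_near <- which.min(abs(branch$param - pbp) +
                        rowSums(abs(as.matrix(branch[, odes$variables]) -
                                      matrix(xbp, nrow(branch), d, byrow = TRUE))))
  ucur <- c(as.numeric(branch[i_near, odes$variables]), branch$param[[i_near]])
  tau_cur <- cont_tangent(fns, ucur[seq_len(d)], ucur[d + 1L])
  w <- v2 - sum(v2 * tau_cur) * tau_cur
  if (sqrt(sum(w^2)) < 1e-8) {
    w <- v1 - sum(v1 * tau_cur) * tau_cur
  }
  if (sqrt(sum(w^2)) < 1e-8) {
    stop("degenerate tangent at the branch point; cannot switch", call. = FALSE)
  }
  w <- w / sqrt(sum(w^2))

  rng <- range(branch$param)
  width <- diff(rng)
  delta <- max(1e-4 * width, 1e-6)
  seed <- NULL
  for (sgn in c(+1, -1)) {
    u0 <- c(xbp, pbp) + sgn * delta * w
    u <- cont_correct(fns, u0, w, u0)
    if (!is.null(u) && sqrt(sum((u - c(xbp, pbp))^2)) > delta / 10) {
      seed <- u; break
    }
  }
  if (is.null(seed)) {
    stop("could not land on the bifurcating branch", call. = FALSE)
  }
  continue_branch(odes, param, params,
                  start_state = seed[seq_len(d)], start_value = seed[d + 1L],
                  range = rng, step = width / 100,
                  state_bounds = attr(branch, "state_bounds"))
}

#' Assemble a bifurcation diagram
#'
#' Orchestrates the full analysis: equilibria are located at several
#' parameter values across the range, each seeds a continuation, branch
#' points trigger a switched continuation along the crossing branch, and all
#' branches are collected with a response expression (a single reactant or a
#' sum/difference of reactants) evaluated at every point.
#'
#' @param x a `reaction_model` (count-form ODEs are derived) or an
#'   `ode_system`.
#' @param param bifurcation parameter name.
#' @param response response expression over the state variables, e.g.
#'   `"A - B"`.
#' @param params named list binding the remaining parameters.
#' @param range length-2 parameter interval.
#' @param lower,upper state-space box used for the equilibrium searches.
#' @param seeds parameter values at which equilibria are sought (default:
#'   five values spanning the range).
#' @return an object of class `bifurcation_diagram`: a list of branches,
#'   the combined special points, and any continuation warnings.
#' @examples
#' fx <- load_fixture("honeybee_reduced")
#' dg <- build_diagram(fx$model, "s", "A - B",
#'                     params = fx$params$fig5_left, range = c(0.5, 5),
#'                     lower = 0, upper = 1)
#' glance(dg)
#' @export
build_diagram <- function(x, param, response, params, range, lower, upper,
                          seeds = NULL) {
  odes <- if (inherits(x, "reaction_model")) derive_odes(x, "counts") else x
  stopifnot(inherits(odes, "ode_system"))
  d <- length(odes$variables)
  range <- sort(as.numeric(range))
  if (is.null(seeds)) seeds <- seq(range[1], range[2], length.out = 5L)
  resp <- if (is.character(response)) q_parse(response) else q_from_lang(response)

  branches <- list()
  warnings_ <- character(0)
  lower <- rep_len(lower, d); upper <- rep_len(upper, d)
  sb <- list(lower = lower - 0.5 * (upper - lower),
             upper = upper + 0.5 * (upper - lower))
  scale <- c(pmax(upper - lower, 1e-12), diff(range))
  # normalized distance from a candidate equilibrium to the polyline of an
  # existing branch (branches are sampled adaptively, so point-to-point
  # proximity is not enough)
  covered <- function(x0, p0) {
    u <- c(x0, p0) / scale
    for (br in branches) {
      P <- cbind(as.matrix(br[, odes$variables, drop = FALSE]), br$param)
      P <- sweep(P, 2, scale, "/")
      if (min_segment_distance(u, P) < 0.02) return(TRUE)
    }
    FALSE
  }

  for (p0 in seeds) {
    eq <- tryCatch(
      find_fixed_points(odes, c(as.list(params),
                                stats::setNames(list(p0), param)),
                        lower, upper),
      error = function(e) NULL)
    if (is.null(eq) || nrow(eq) == 0L) next
    for (i in seq_len(nrow(eq))) {
      x0 <- as.numeric(eq[i, odes$variables])
      if (covered(x0, p0)) next
      br <- tryCatch(
        continue_branch(odes, param, params, x0, p0, range,
                        state_bounds = sb),
        error = function(e) {
          warnings_ <<- c(warnings_, conditionMessage(e)); NULL
        })
      if (!is.null(br)) branches[[length(branches) + 1L]] <- br
    }
  }

  # switch at branch points
  n_primary <- length(branches)
  for (b in seq_len(n_primary)) {
    sp <- attr(branches[[b]], "special_points")
    bps <- which(sp$kind == "BP")
    for (k in seq_along(bps)) {
      sw <- tryCatch(switch_branch(branches[[b]], which = k),
                     error = function(e) {
                       warnings_ <<- c(warnings_, conditionMessage(e)); NULL
                     })
      if (!is.null(sw)) {
        mid <- sw[which.max(abs(sw$param - sp$param[bps[k]])), ]
        if (!covered(as.numeric(mid[, odes$variables]), mid$param[[1]])) {
          branches[[length(branches) + 1L]] <- sw
        }
      }
    }
  }

  eval_resp <- function(br) {
    vapply(seq_len(nrow(br)), function(i) {
      q_eval(resp, as.list(stats::setNames(as.numeric(br[i, odes$variables]),
                                           odes$variables)))
    }, numeric(1))
  }
  branches <- lapply(branches, function(br) {
    br$response <- eval_resp(br)
    br
  })
  specials <- dplyr::bind_rows(lapply(seq_along(branches), function(b) {
    sp <- attr(branches[[b]], "special_points")
    if (nrow(sp) > 0L) dplyr::mutate(sp, branch_id = b) else NULL
  }))
  structure(list(branches = branches, special_points = specials,
                 param = param, response = response, odes = odes,
                 range = range, warnings = warnings_),
            class = "bifurcation_diagram")
}

# smallest Euclidean distance from point u to the polyline with vertex rows P
min_segment_distance <- function(u, P) {
  n <- nrow(P)
  if (n == 0L) return(Inf)
  if (n == 1L) return(sqrt(sum((u - P[1, ])^2)))
  best <- Inf
  for (i in seq_len(n - 1L)) {
    a <- P[i, ]; b <- P[i + 1L, ]
    ab <- b - a
    L2 <- sum(ab^2)
    tt <- if (L2 == 0) 0 else max(0, min(1, sum((u - a) * ab) / L2))
    best <- min(best, sum((u - a - tt * ab)^2))
  }
  sqrt(best)
}

#' @export
print.bifurcation_diagram <- function(x, ...) {
  cat("<bifurcation_diagram> parameter:", x$param,
      " response:", if (is.character(x$response)) x$response else
        deparse(x$response), "\n")
  cat(length(x$branches), "branch(es)\n")
  if (nrow(x$special_points) > 0L) {
    cat("special points:\n")
    print(as.data.frame(x$special_points))
  } else {
    cat("no special points detected\n")
  }
  if (length(x$warnings) > 0L) {
    cat("warnings:", paste(x$warnings, collapse = "; "), "\n")
  }
  invisible(x)
}
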