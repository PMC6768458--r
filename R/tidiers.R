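# broom-style tidiers for the fitted/derived result objects.

#' Tidy a stationary covariance result
#'
#' One row per covariance entry of the stationary fluctuation matrix C.
#' @param x a `covariance_result`.
#' @param ... unused.
#' @return a tibble with columns `var_i`, `var_j`, `covariance`.
#' @export
tidy.covariance_result <- function(x, ...) {
  sp <- x$species
  out <- expand.grid(var_i = sp, var_j = sp, stringsAsFactors = FALSE)
  out$covariance <- as.numeric(x$C[cbind(match(out$var_i, sp),
                                         match(out$var_j, sp))])
  tibble::as_tibble(out)
}

#' @rdname tidy.covariance_result
#' @export
glance.covariance_result <- function(x, ...) {
  tibble::tibble(
    dimension = length(x$species),
    max_eigenvalue_re = max(Re(x$eigenvalues)),
    lyapunov_residual = x$lyapunov_residual,
    total_variance = sum(diag(x$C))
  )
}

#' Tidy a linear-noise expansion
#'
#' Long form of the symbolic drift (A) and diffusion (B) matrices.
#' @param x a `linear_noise` object.
#' @param ... unused.
#' @return a tibble with columns `matrix`, `var_i`, `var_j`, `expression`.
#' @export
tidy.linear_noise <- function(x, ...) {
  sp <- x$species
  rows <- list()
  for (m in c("A", "B")) {
    M <- x[[m]]
    for (i in seq_along(sp)) for (j in seq_along(sp)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        matrix = m, var_i = sp[i], var_j = sp[j],
        expression = q_deparse(M[[i, j]]))
    }
  }
  dplyr::bind_rows(rows)
}

#' Tidy a bifurcation diagram
#'
#' All branches in long form, one row per continuation point.
#' @param x a `bifurcation_diagram`.
#' @param ... unused.
#' @return a tibble with `branch_id`, `param`, the state variables,
#'   `response` and `stable`.
#' @export
tidy.bifurcation_diagram <- function(x, ...) {
  dplyr::bind_rows(lapply(seq_along(x$branches), function(b) {
    br <- tibble::as_tibble(x$branches[[b]])
    br$branch_id <- b
    br
  }))
}

#' @rdname tidy.bifurcation_diagram
#' @export
glance.bifurcation_diagram <- function(x, ...) {
  sp <- x$special_points
  tibble::tibble(
    n_branches = length(x$branches),
    n_bp = sum(sp$kind == "BP"),
    n_lp = sum(sp$kind == "LP"),
    n_warnings = length(x$warnings)
  )
}

#' Tidy a simulation ensemble
#'
#' One row per run and species with the final counts.
#' @param x an `ensemble_result`.
#' @param ... unused.
#' @return a tibble with `run`, `species`, `count`.
#' @export
tidy.ensemble_result <- function(x, ...) {
  fs <- x$final_states
  out <- expand.grid(run = seq_len(nrow(fs)), species = colnames(fs),
                     stringsAsFactors = FALSE)
  out$count <- as.numeric(fs[cbind(out$run, match(out$species, colnames(fs)))])
  tibble::as_tibble(out[order(out$run), ])
}

#' @rdname tidy.ensemble_result
#' @export
glance.ensemble_result <- function(x, ...) {
  tibble::tibble(
    runs = x$runs, V = x$V, t_max = x$t_max, engine = x$engine,
    seed = x$seed
  )
}
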