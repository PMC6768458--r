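# ggplot2 display methods.  Each result type knows how to draw itself;
# autoplot() returns the plot object for further styling.

#' Plot a trajectory
#'
#' Lines of every state variable against time; works for integrated ODE
#' solutions, SSA jump trajectories and agent-count trajectories.
#' @param object an `rxn_trajectory` (or subclass).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.rxn_trajectory <- function(object, ...) {
  vars <- attr(object, "variables")
  long <- tidyr_longer(object, vars)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value,
                                     colour = .data$variable)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time", y = "abundance", colour = NULL) +
    ggplot2::theme_minimal()
}

# minimal wide-to-long without importing tidyr
tidyr_longer <- function(df, vars) {
  dplyr::bind_rows(lapply(vars, function(v) {
    tibble::tibble(t = df$t, variable = v, value = df[[v]])
  }))
}

#' Plot a sampled vector field
#'
#' Arrows of the drift at each lattice node, shaded by speed; located fixed
#' points (when attached) are overlaid using the conventional glyphs: filled
#' circles for stable points, open circles for unstable, open squares for
#' saddles.
#' @param object an `rxn_field` from [sample_field()].
#' @param arrow_scale multiplier applied to the normalised arrows.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.rxn_field <- function(object, arrow_scale = 0.8, ...) {
  vars <- attr(object, "variables")
  if (length(vars) != 2L) {
    stop("field plotting needs a 2-dimensional system", call. = FALSE)
  }
  v1 <- vars[1]; v2 <- vars[2]
  df <- tibble::as_tibble(object)
  span1 <- diff(range(df[[v1]])) / max(1, sqrt(nrow(df)))
  mx <- max(df$speed, 1e-12)
  df$xend <- df[[v1]] + arrow_scale * span1 * df[[paste0("d", v1)]] / mx
  df$yend <- df[[v2]] + arrow_scale * span1 * df[[paste0("d", v2)]] / mx
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data[[v1]], y = .data[[v2]])) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$xend, yend = .data$yend,
                                       colour = .data$speed),
                          arrow = ggplot2::arrow(length = ggplot2::unit(1.5, "mm"))) +
    ggplot2::labs(x = v1, y = v2) +
    ggplot2::theme_minimal()
  fp <- attr(object, "fixed_points")
  if (!is.null(fp) && nrow(fp) > 0L) {
    fp <- tibble::as_tibble(fp)
    fp$shape <- c(stable = 16, unstable = 1, saddle = 0)[fp$classification]
    p <- p + ggplot2::geom_point(data = fp,
                                 ggplot2::aes(x = .data[[v1]], y = .data[[v2]]),
                                 shape = fp$shape, size = 3,
                                 colour = "darkgreen")
  }
  p
}

#' Plot a bifurcation diagram
#'
#' Response against the bifurcation parameter: solid lines for stable
#' segments, dashed for unstable, with LP/BP markers labelled.
#' @param object a `bifurcation_diagram`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.bifurcation_diagram <- function(object, ...) {
  long <- tidy.bifurcation_diagram(object)
  long$stability <- ifelse(long$stable, "stable", "unstable")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$param, y = .data$response,
                                          group = .data$branch_id,
                                          linetype = .data$stability)) +
    ggplot2::geom_path() +
    ggplot2::scale_linetype_manual(values = c(stable = "solid",
                                              unstable = "dashed")) +
    ggplot2::labs(x = object$param,
                  y = if (is.character(object$response)) object$response else
                    "response",
                  linetype = NULL) +
    ggplot2::theme_minimal()
  sp <- object$special_points
  if (!is.null(sp) && nrow(sp) > 0L) {
    vars <- object$odes$variables
    resp <- if (is.character(object$response)) q_parse(object$response) else
      q_from_lang(object$response)
    sp$response <- vapply(seq_len(nrow(sp)), function(i) {
      q_eval(resp, as.list(stats::setNames(as.numeric(sp[i, vars]), vars)))
    }, numeric(1))
    p <- p +
      ggplot2::geom_point(data = sp, inherit.aes = FALSE,
                          ggplot2::aes(x = .data$param, y = .data$response),
                          size = 2.5, colour = "red") +
      ggplot2::geom_text(data = sp, inherit.aes = FALSE,
                         ggplot2::aes(x = .data$param, y = .data$response,
                                      label = .data$kind),
                         vjust = -1, size = 3)
  }
  p
}

#' Plot an ensemble's final-state distribution
#'
#' For two or more species: a scatter of per-run final states of the first
#' two species with the mean and the 1-sigma covariance ellipse; for one
#' species: a histogram of final counts.
#' @param object an `ensemble_result`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.ensemble_result <- function(object, ...) {
  fs <- tibble::as_tibble(as.data.frame(object$final_states))
  sp <- object$species
  if (length(sp) == 1L) {
    return(ggplot2::ggplot(fs, ggplot2::aes(x = .data[[sp[1]]])) +
             ggplot2::geom_histogram(binwidth = 1) +
             ggplot2::labs(x = sp[1], y = "runs") +
             ggplot2::theme_minimal())
  }
  v1 <- sp[1]; v2 <- sp[2]
  ell <- covariance_ellipse_points(object$mean[c(v1, v2)],
                                   object$covariance[c(v1, v2), c(v1, v2)])
  ggplot2::ggplot(fs, ggplot2::aes(x = .data[[v1]], y = .data[[v2]])) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_path(data = ell, ggplot2::aes(x = .data$x, y = .data$y),
                       colour = "darkgreen") +
    ggplot2::annotate("point", x = object$mean[[v1]], y = object$mean[[v2]],
                      colour = "darkgreen", size = 3) +
    ggplot2::labs(x = v1, y = v2) +
    ggplot2::theme_minimal()
}

# 1-sigma ellipse outline of a 2x2 covariance matrix
covariance_ellipse_points <- function(center, C, n = 100L) {
  ec <- eigen((C + t(C)) / 2, symmetric = TRUE)
  r <- sqrt(pmax(ec$values, 0))
  th <- seq(0, 2 * pi, length.out = n)
  pts <- ec$vectors %*% rbind(r[1] * cos(th), r[2] * sin(th))
  tibble::tibble(x = center[[1]] + pts[1, ], y = center[[2]] + pts[2, ])
}

#' @export
plot.rxn_trajectory <- function(x, ...) print(autoplot.rxn_trajectory(x, ...))

#' @export
plot.bifurcation_diagram <- function(x, ...) {
  print(autoplot.bifurcation_diagram(x, ...))
}

#' @export
plot.ensemble_result <- function(x, ...) print(autoplot.ensemble_result(x, ...))
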