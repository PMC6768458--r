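#' Export analysis results to CSV or JSON
#'
#' Schema-stable serialization for external analysis: tabular results
#' (trajectories, fields, fixed points, branches) as CSV or JSON records;
#' structured results (covariance, linear-noise, ensembles, diagrams) as
#' JSON objects with symbolic expressions rendered as canonical strings.
#' Floats are written at full (17 significant digit) precision and every file
#' carries a metadata block (object class, seed when known, package version).
#'
#' @param result any rxnscale result object or data frame.
#' @param path output file path.
#' @param format `"csv"` or `"json"` (default: from the file extension).
#' @return `path`, invisibly.
#' @export
export_results <- function(result, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  seed <- attr(result, "seed")
  if (is.null(seed) && is.list(result) && !is.data.frame(result)) {
    seed <- result$seed
  }
  meta <- list(
    class = class(result)[1],
    package = "rxnscale",
    version = as.character(utils::packageVersion("rxnscale")),
    seed = seed
  )
  if (format == "csv") {
    df <- result_as_table(result)
    utils::write.csv(as.data.frame(df), path, row.names = FALSE)
    return(invisible(path))
  }
  payload <- result_as_json(result)
  payload$metadata <- meta[!vapply(meta, is.null, logical(1))]
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

result_as_table <- function(result) {
  if (is.data.frame(result)) return(result)
  if (inherits(result, "ensemble_result")) return(tidy.ensemble_result(result))
  if (inherits(result, "bifurcation_diagram")) {
    return(tidy.bifurcation_diagram(result))
  }
  if (inherits(result, "covariance_result")) {
    return(tidy.covariance_result(result))
  }
  stop("no tabular form for objects of class ", class(result)[1], call. = FALSE)
}

result_as_json <- function(result) {
  if (inherits(result, "covariance_result")) {
    return(list(
      species = result$species,
      A = unname(as.data.frame(result$A)),
      B = unname(as.data.frame(result$B)),
      C = unname(as.data.frame(result$C)),
      fixed_point = as.list(result$fixed_point),
      ellipse = list(center = as.list(result$ellipse$center),
                     radii = result$ellipse$radii,
                     axes = unname(as.data.frame(result$ellipse$axes))),
      lyapunov_residual = result$lyapunov_residual
    ))
  }
  if (inherits(result, "linear_noise")) {
    return(list(
      species = result$species,
      macroscopic = lapply(result$macroscopic$drift, q_deparse),
      A = matrix_deparse(result$A),
      B = matrix_deparse(result$B)
    ))
  }
  if (inherits(result, "ensemble_result")) {
    return(list(
      species = result$species, runs = result$runs, V = result$V,
      t_max = result$t_max, seed = result$seed, engine = result$engine,
      mean = as.list(result$mean),
      covariance = unname(as.data.frame(result$covariance)),
      final_states = unname(as.data.frame(result$final_states))
    ))
  }
  if (inherits(result, "bifurcation_diagram")) {
    return(list(
      param = result$param,
      response = if (is.character(result$response)) result$response else
        deparse(result$response),
      branches = lapply(result$branches, function(br)
        as.list(tibble::as_tibble(br))),
      special_points = as.list(result$special_points),
      warnings = result$warnings
    ))
  }
  if (is.data.frame(result)) return(list(data = as.list(result)))
  stop("no JSON form for objects of class ", class(result)[1], call. = FALSE)
}

matrix_deparse <- function(M) {
  lapply(seq_len(nrow(M)), function(i) {
    vapply(seq_len(ncol(M)), function(j) q_deparse(M[[i, j]]), character(1))
  })
}
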