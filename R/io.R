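#' Read flow samples from CSV
#'
#' Reads a per-event table with mandatory header `sample_id,intensity`
#' (comma separator, '.' decimal, UTF-8), one event per row, and returns
#' one [flow_sample()] per distinct `sample_id`, preserving row order.
#' Non-positive, non-finite or unparsable intensities are rejected with
#' row-numbered messages (rows counted over data rows, excluding the
#' header).
#'
#' @param path path to the CSV file.
#' @return Named list of [flow_sample()] objects.
#' @export
read_flow_csv <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character"),
    error = function(e) stopf("cannot parse %s: %s", path, conditionMessage(e))
  )
  missing_cols <- setdiff(c("sample_id", "intensity"), names(df))
  if (length(missing_cols) > 0) {
    stopf("%s: missing column '%s'", path, missing_cols[1])
  }
  if (nrow(df) == 0) stopf("%s: no data rows", path)
  v <- suppressWarnings(as.numeric(df$intensity))
  bad <- which(is.na(v))
  if (length(bad) > 0) {
    stopf("%s: row %d, column intensity: unparsable value '%s'",
          path, bad[1], df$intensity[bad[1]])
  }
  bad <- which(!is.finite(v) | v <= 0)
  if (length(bad) > 0) {
    stopf("%s: row %d, column intensity: value %s is not a positive finite number",
          path, bad[1], df$intensity[bad[1]])
  }
  ids <- unique(df$sample_id)
  out <- lapply(ids, function(id) flow_sample(v[df$sample_id == id], id))
  names(out) <- ids
  out
}

#' Write flow samples to CSV
#'
#' Writes the `sample_id,intensity` schema read by [read_flow_csv()].
#' Intensities are formatted with 17 significant digits so a write-read
#' round trip reproduces values exactly.
#'
#' @param samples a [flow_sample()] or list of them.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_flow_csv <- function(samples, path) {
  if (inherits(samples, "flow_sample")) samples <- list(samples)
  df <- do.call(rbind, lapply(samples, function(s) {
    data.frame(sample_id = s$sample_id,
               intensity = sprintf("%.17g", s$intensities),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a lineage dataset to CSV
#'
#' Columns: `generation`, `cell_index`, `parent_index`, `outcome` (I|J|K),
#' `factor`, `activity`.
#'
#' @param lineage a `lineage_dataset` from [generate_lineage_dataset()].
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_lineage_csv <- function(lineage, path) {
  if (!inherits(lineage, "lineage_dataset")) {
    stopf("lineage: must be a lineage_dataset")
  }
  utils::write.csv(lineage$records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a per-generation trajectory summary to CSV
#'
#' Columns: `generation`, `n_cells`, `mean`, `sd`, `p5`, `p95`.
#'
#' @param trajectory a `population_trajectory`.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_generation_summary_csv <- function(trajectory, path) {
  if (!inherits(trajectory, "population_trajectory")) {
    stopf("trajectory: must be a population_trajectory")
  }
  utils::write.csv(summary(trajectory), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Strip non-serializable bulk from result objects for JSON reports.
report_body <- function(x) {
  if (inherits(x, "mixture_fit")) {
    list(k = x$k, weights = x$weights, means = x$means, sds = x$sds,
         log_likelihood = x$log_likelihood, bic = x$bic, n_iter = x$n_iter,
         converged = x$converged, n = x$n,
         candidates = x$candidates)
  } else if (inherits(x, "gate_result")) {
    list(low_threshold = x$low_threshold, high_threshold = x$high_threshold,
         low_fraction = x$low_fraction, high_fraction = x$high_fraction,
         n_low = length(x$low_indices), n_high = length(x$high_indices),
         n = x$n, low_indices = x$low_indices, high_indices = x$high_indices)
  } else if (inherits(x, "convergence_report")) {
    list(metric = x$metric, tolerance = x$tolerance,
         per_generation_distance = x$per_generation_distance,
         divisions_to_convergence = x$divisions_to_convergence,
         per_rep_divisions = x$per_rep_divisions, n_reps = x$n_reps,
         max_generations = x$max_generations,
         gate_fraction = x$gate_fraction)
  } else if (inherits(x, "estimation_result")) {
    list(t_hat = x$t_hat, grid = x$grid, objective = x$objective,
         n_reps = x$n_reps, gate_fraction = x$gate_fraction)
  } else {
    x
  }
}

#' Write a JSON report with run provenance
#'
#' Serializes a result object together with the seed, the package version,
#' the resolved configuration and its hash, so every artifact records how
#' it was produced.
#'
#' @param x result object (`mixture_fit`, `gate_result`,
#'   `convergence_report`, `estimation_result`, or a plain list).
#' @param path output path.
#' @param seed the seed the run used.
#' @param config named list of resolved settings (optional).
#' @return The path, invisibly.
#' @export
write_report_json <- function(x, path, seed = NULL, config = NULL) {
  payload <- list(
    package = "mitofluct",
    version = as.character(utils::packageVersion("mitofluct")),
    seed = seed,
    config = config,
    config_hash = if (is.null(config)) NULL else config_hash(config),
    result = report_body(x)
  )
  payload <- payload[!vapply(payload, is.null, logical(1))]
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
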