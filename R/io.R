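#' Read a patient table from delimited text
#'
#' Expects one row per patient with 0/1 factor columns, `time_months` and
#' `event`, plus optional `patient_id` and `cohort` columns.  Lines
#' starting with `#` are treated as comments (the simulator writes its seed
#' there).
#'
#' @param path File path.
#' @param sep Field delimiter, default tab.
#' @param na Missing-value token(s), default empty string or literal `NA`.
#' @return Patient data frame, validated.
#' @export
read_patient_table <- function(path, sep = "\t", na = c("", "NA")) {
  d <- utils::read.table(path, header = TRUE, sep = sep, na.strings = na,
                         stringsAsFactors = FALSE, comment.char = "#")
  .check_cohort(d, intersect(candidate_factors(), names(d)))
  d
}

#' Write a patient table as delimited text
#'
#' @param patients Patient data frame.
#' @param path File path.
#' @param sep Field delimiter, default tab.
#' @param header_comment Optional comment line(s) written before the
#'   header, e.g. recording the simulation seed.
#' @export
write_patient_table <- function(patients, path, sep = "\t",
                                header_comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) {
    writeLines(paste0("# ", header_comment), con)
  }
  utils::write.table(patients, con, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Serialize a fitted risk model to JSON
#'
#' Writes the score weights, the reference (minimum) chi-square, the
#' cutoff, and provenance (package version, timestamp, optional seed).
#'
#' @param model An `lnm_model` (or list with `score_table` and `cutoff`).
#' @param path Output path.
#' @param seed Optional seed recorded in provenance.
#' @export
write_model_json <- function(model, path, seed = NULL) {
  obj <- list(
    weights = as.list(model$score_table$weights),
    reference_chi2 = model$score_table$reference_chi2,
    cutoff = model$cutoff,
    provenance = list(
      package = "lnmrisk",
      version = as.character(utils::packageVersion("lnmrisk")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      seed = seed))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a risk model back from JSON
#'
#' @param path Path written by [write_model_json()].
#' @return An `lnm_model` usable by [classify_risk()] and
#'   [evaluate_model()].
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  st <- structure(list(weights = unlist(obj$weights),
                       reference_chi2 = obj$reference_chi2),
                  class = "score_table")
  structure(list(score_table = st, cutoff = obj$cutoff,
                 provenance = obj$provenance),
            class = "lnm_model")
}

#' Serialize an evaluation to a JSON report
#'
#' @param evaluation An `lnm_evaluation` from [evaluate_model()].
#' @param path Output path.
#' @param config Optional named list echoed into the report (e.g. seed,
#'   horizon); a stable hash of it is embedded for reproducibility checks.
#' @export
write_evaluation_json <- function(evaluation, path, config = NULL) {
  km_block <- function(km) {
    if (is.null(km)) return(NULL)
    as.list(km$lookup)
  }
  obj <- list(
    group_sizes = as.list(evaluation$group_sizes),
    confusion = evaluation$confusion,
    auc = evaluation$auc,
    km_cumulative_incidence = list(high = km_block(evaluation$km_high),
                                   low = km_block(evaluation$km_low)),
    contrast = evaluation$contrast,
    provenance = list(
      package = "lnmrisk",
      version = as.character(utils::packageVersion("lnmrisk")),
      config = config,
      config_hash = if (!is.null(config)) {
        sum(utf8ToInt(paste(names(config), unlist(config), collapse = ";")))
      }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
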