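#' Simulate cohorts and write them as patient tables
#'
#' Wraps [generate_paperlike_pair()] (or a single [generate_cohort()] when
#' `n` is given) and writes delimited patient tables with the seed recorded
#' in a header comment.
#'
#' @param out_training,out_validation Output paths.
#' @param seed Integer seed.
#' @param n Optional single-cohort size; when `NULL` (default) the
#'   training/validation pair of sizes 192 and 209 is written.
#' @param sep Field delimiter.
#' @return Invisibly, the written path(s).
#' @export
cmd_simulate <- function(out_training, out_validation = NULL, seed = 1L,
                         n = NULL, sep = "\t") {
  if (is.null(n)) {
    pair <- generate_paperlike_pair(seed)
    write_patient_table(pair$training, out_training, sep = sep,
                        header_comment = paste("seed:", seed))
    if (!is.null(out_validation)) {
      write_patient_table(pair$validation, out_validation, sep = sep,
                          header_comment = paste("seed:", seed))
    }
    invisible(c(out_training, out_validation))
  } else {
    co <- generate_cohort(cohort_spec(n = n, seed = seed))
    write_patient_table(co, out_training, sep = sep,
                        header_comment = paste("seed:", seed))
    invisible(out_training)
  }
}

#' Build a risk model from a training table and write the model JSON
#'
#' Runs screening, the multivariate Cox fit, weight derivation and cutoff
#' selection on a patient table, then serializes the model.  With
#' `chi2_bypass`, a named vector of per-factor chi-square values is fed
#' directly into [derive_weights()] (no patient data needed); the cutoff
#' then defaults to half the maximum attainable score unless patients are
#' also supplied.
#'
#' @param in_table Path to the training patient table (may be `NULL` with
#'   `chi2_bypass`).
#' @param out_model Output path for the model JSON.
#' @param seed Seed recorded in provenance.
#' @param alpha Screening significance level.
#' @param ties Cox tie-handling method.
#' @param chi2_bypass Optional named numeric vector of Wald chi-square
#'   values.
#' @param sep Field delimiter of the input table.
#' @return Invisibly, the fitted `lnm_model`.
#' @export
cmd_build <- function(in_table, out_model, seed = 1L, alpha = 0.05,
                      ties = "efron", chi2_bypass = NULL, sep = "\t") {
  if (!is.null(chi2_bypass)) {
    st <- derive_weights(data.frame(factor = names(chi2_bypass),
                                    wald_chi2 = as.numeric(chi2_bypass)))
    model <- structure(list(score_table = st,
                            cutoff = sum(st$weights) / 2,
                            selected_factors = names(chi2_bypass)),
                       class = "lnm_model")
    if (!is.null(in_table)) {
      patients <- read_patient_table(in_table, sep = sep)
      sc <- total_score(patients, st)
      cut <- select_cutoff(sc, patients$event)
      model$cutoff <- cut$cutoff
      model$trend_statistic <- cut$trend_statistic
    }
  } else {
    patients <- read_patient_table(in_table, sep = sep)
    model <- build_risk_model(patients,
                              factors = intersect(candidate_factors(),
                                                  names(patients)),
                              alpha = alpha, ties = ties)
  }
  write_model_json(model, out_model, seed = seed)
  invisible(model)
}

#' Evaluate a stored model on a cohort table and write a JSON report
#'
#' @param in_model Path to a model JSON.
#' @param in_table Path to the cohort patient table.
#' @param out_report Output path for the evaluation JSON.
#' @param horizon_months Evaluation horizon, default 60.
#' @param km_lookup_months Kaplan--Meier lookup times.
#' @param sep Field delimiter of the input table.
#' @return Invisibly, the `lnm_evaluation`.
#' @export
cmd_evaluate <- function(in_model, in_table, out_report,
                         horizon_months = 60,
                         km_lookup_months = c(12, 24, 60), sep = "\t") {
  model <- read_model_json(in_model)
  patients <- read_patient_table(in_table, sep = sep)
  miss <- setdiff(names(model$score_table$weights), names(patients))
  if (length(miss)) {
    stop("cohort table lacks model factor column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  ev <- evaluate_model(patients, model, horizon_months = horizon_months,
                       km_lookup_months = km_lookup_months)
  write_evaluation_json(ev, out_report,
                        config = list(horizon_months = horizon_months,
                                      model = in_model, table = in_table))
  invisible(ev)
}

#' Score new patients against a stored model
#'
#' @param in_model Path to a model JSON.
#' @param in_table Path to a patient table (needs only the model's factor
#'   columns).
#' @param out_table Output path for the per-patient score/group table.
#' @param sep Field delimiter.
#' @return Invisibly, the classification data frame.
#' @export
cmd_apply <- function(in_model, in_table, out_table, sep = "\t") {
  model <- read_model_json(in_model)
  patients <- utils::read.table(in_table, header = TRUE, sep = sep,
                                stringsAsFactors = FALSE,
                                comment.char = "#")
  cls <- classify_risk(patients, model)
  utils::write.table(cls, out_table, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(cls)
}
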