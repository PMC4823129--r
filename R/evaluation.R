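#' Assign patients to risk groups under a fitted model
#'
#' Scores each patient with the model's score table and labels the patient
#' `"high"` when the total score strictly exceeds the cutoff; a score equal
#' to the cutoff is low risk.
#'
#' @param patients Patient data frame carrying all model factors.
#' @param model An `lnm_model` from [build_risk_model()], or any list with
#'   elements `score_table` and `cutoff`.
#' @return Data frame with `patient_id` (if present), `total_score`,
#'   `group`.
#' @export
classify_risk <- function(patients, model) {
  sc <- total_score(patients, model$score_table)
  grp <- ifelse(sc > model$cutoff, "high", "low")
  out <- data.frame(total_score = sc, group = grp,
                    stringsAsFactors = FALSE)
  if ("patient_id" %in% names(patients)) {
    out <- cbind(patient_id = patients$patient_id, out)
  }
  out
}

#' Confusion metrics of the risk grouping at a follow-up horizon
#'
#' Classifies each patient at a time horizon: a *case* developed metastasis
#' on or before the horizon; a *control* was followed event-free through
#' the horizon.  Patients censored event-free before the horizon carry no
#' horizon-status information under this convention and are excluded from
#' the evaluable set (no inverse-probability-of-censoring weighting is
#' applied).  High risk plays the role of test-positive.
#'
#' @param patients Patient data frame (`time_months`, `event`).
#' @param groups Character vector `"high"`/`"low"`, one per patient, e.g.
#'   the `group` column of [classify_risk()].
#' @param horizon_months Horizon, default 60 (five years).
#' @return List with `horizon_months`, counts `tp`, `fp`, `tn`, `fn`,
#'   `n_evaluable`, and `sensitivity`, `specificity`, `ppv`, `npv`
#'   (fractions; `NA` with a warning when undefined).
#' @export
horizon_confusion <- function(patients, groups, horizon_months = 60) {
  .check_cohort(patients)
  if (horizon_months <= 0) stop("horizon must be > 0", call. = FALSE)
  if (length(groups) != nrow(patients)) {
    stop("groups length does not match patients", call. = FALSE)
  }
  case <- patients$event == 1 & patients$time_months <= horizon_months
  control <- !case & patients$time_months >= horizon_months
  evaluable <- case | control
  hi <- groups == "high"
  tp <- sum(case & hi); fn <- sum(case & !hi)
  fp <- sum(control & hi); tn <- sum(control & !hi)
  div <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (empty denominator)")
      return(NA_real_)
    }
    num / den
  }
  list(horizon_months = horizon_months, tp = tp, fp = fp, tn = tn, fn = fn,
       n_evaluable = sum(evaluable),
       sensitivity = div(tp, tp + fn, "sensitivity"),
       specificity = div(tn, tn + fp, "specificity"),
       ppv = div(tp, tp + fp, "PPV"),
       npv = div(tn, tn + fn, "NPV"))
}

#' Area under the ROC curve of a continuous score
#'
#' Computes the AUC as the Mann--Whitney probability that a randomly chosen
#' case scores higher than a randomly chosen control, with ties credited
#' one half.
#'
#' @param scores Numeric scores.
#' @param case_status 0/1 case indicators, same length.
#' @return AUC in \[0, 1\].
#' @export
score_auc <- function(scores, case_status) {
  if (length(scores) != length(case_status)) {
    stop("scores and case_status differ in length", call. = FALSE)
  }
  if (!all(case_status %in% c(0, 1))) {
    stop("case_status must be 0/1", call. = FALSE)
  }
  n1 <- sum(case_status == 1); n0 <- sum(case_status == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present", call. = FALSE)
  r <- rank(scores)               # midranks give the 0.5 tie credit
  (sum(r[case_status == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Kaplan--Meier cumulative incidence of metastasis
#'
#' Estimates the cumulative incidence of lymph node metastasis as one minus
#' the Kaplan--Meier survival function of time-to-metastasis, treating all
#' non-metastasis exits as censoring.
#'
#' @param patients Patient data frame (`time_months`, `event`).
#' @param lookup_months Times at which to read the curve, default
#'   `c(12, 24, 60)`.
#' @return List with `times`, `cumulative_incidence` (right-continuous step
#'   function values at `times`) and `lookup` (named vector of incidences
#'   at `lookup_months`).
#' @export
km_cumulative_incidence <- function(patients, lookup_months = c(12, 24, 60)) {
  .check_cohort(patients)
  fit <- survival::survfit(
    survival::Surv(time_months, event) ~ 1, data = patients)
  times <- fit$time
  ci <- 1 - fit$surv
  at <- summary(fit, times = lookup_months, extend = TRUE)
  list(times = times, cumulative_incidence = ci,
       lookup = stats::setNames(1 - at$surv, paste0("m", lookup_months)))
}

#' Two-group log-rank test
#'
#' @param patients Patient data frame (`time_months`, `event`).
#' @param groups Two-level grouping vector, one entry per patient.
#' @return List with `statistic` (chi-square, 1 df) and `p_value`.  With no
#'   events at all the statistic is 0 and p is 1, with a warning.
#' @export
logrank_test <- function(patients, groups) {
  .check_cohort(patients)
  if (length(unique(groups)) != 2L) {
    stop("groups must have exactly two levels", call. = FALSE)
  }
  if (sum(patients$event) == 0) {
    warning("no events in either group; log-rank undefined")
    return(list(statistic = 0, p_value = 1))
  }
  d <- data.frame(time_months = patients$time_months,
                  event = patients$event, g = groups)
  sd <- survival::survdiff(
    survival::Surv(time_months, event) ~ g, data = d)
  list(statistic = unname(sd$chisq),
       p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Hazard ratio of the high-risk versus low-risk group
#'
#' Fits a single-covariate Cox model on the risk-group indicator (high vs
#' low) and combines the Wald hazard ratio and CI with the log-rank test.
#'
#' @param patients Patient data frame (`time_months`, `event`).
#' @param groups Character vector `"high"`/`"low"`.
#' @param ties Cox tie-handling method.
#' @return List with `hazard_ratio`, `ci95`, `logrank_statistic`,
#'   `logrank_p`, and a `separation` flag (a group without events makes the
#'   estimate effectively infinite).
#' @export
group_hazard_ratio <- function(patients, groups, ties = "efron") {
  d <- cbind(patients, .risk_high = as.integer(groups == "high"))
  u <- univariate_ph(d, ".risk_high", ties = ties)
  lr <- logrank_test(patients, groups)
  list(hazard_ratio = u$hazard_ratio, ci95 = u$ci95,
       logrank_statistic = lr$statistic, logrank_p = lr$p_value,
       separation = u$separation)
}

#' Evaluate a fitted risk model on a cohort
#'
#' Full evaluation block: risk-group sizes, horizon confusion metrics,
#' AUC of the continuous score against horizon case status, Kaplan--Meier
#' cumulative incidence per risk group, log-rank comparison, and the
#' high-vs-low hazard ratio.
#'
#' @param patients Cohort data frame.
#' @param model An `lnm_model`.
#' @param horizon_months Evaluation horizon, default 60.
#' @param km_lookup_months Kaplan--Meier lookup times, default
#'   `c(12, 24, 60)`.
#' @return List of class `lnm_evaluation` with elements `groups` (the
#'   classification table), `group_sizes`, `confusion`, `auc`,
#'   `km_high`, `km_low`, `contrast`.
#' @export
evaluate_model <- function(patients, model, horizon_months = 60,
                           km_lookup_months = c(12, 24, 60)) {
  cls <- classify_risk(patients, model)
  conf <- horizon_confusion(patients, cls$group, horizon_months)
  case <- patients$event == 1 & patients$time_months <= horizon_months
  control <- !case & patients$time_months >= horizon_months
  ev <- case | control
  auc <- if (any(case[ev]) && any(!case[ev])) {
    score_auc(cls$total_score[ev], as.integer(case[ev]))
  } else NA_real_
  hi <- cls$group == "high"
  km_high <- if (any(hi)) {
    km_cumulative_incidence(patients[hi, , drop = FALSE], km_lookup_months)
  } else NULL
  km_low <- if (any(!hi)) {
    km_cumulative_incidence(patients[!hi, , drop = FALSE], km_lookup_months)
  } else NULL
  contrast <- if (length(unique(cls$group)) == 2L) {
    group_hazard_ratio(patients, cls$group)
  } else NULL
  structure(list(groups = cls,
                 group_sizes = c(high = sum(hi), low = sum(!hi)),
                 confusion = conf, auc = auc,
                 km_high = km_high, km_low = km_low,
                 contrast = contrast),
            class = "lnm_evaluation")
}

#' @export
print.lnm_evaluation <- function(x, ...) {
  cat("Risk-model evaluation (horizon", x$confusion$horizon_months,
      "months)\n")
  cat("  groups: high =", x$group_sizes["high"],
      ", low =", x$group_sizes["low"], "\n")
  cat(sprintf("  sensitivity %.3f  specificity %.3f  PPV %.3f  NPV %.3f\n",
              x$confusion$sensitivity, x$confusion$specificity,
              x$confusion$ppv, x$confusion$npv))
  cat(sprintf("  AUC %.3f  (n evaluable %d)\n", x$auc,
              x$confusion$n_evaluable))
  if (!is.null(x$contrast)) {
    cat(sprintf("  high vs low HR %.3f (95%% CI %.3f-%.3f), log-rank p %.3g\n",
                x$contrast$hazard_ratio, x$contrast$ci95[1],
                x$contrast$ci95[2], x$contrast$logrank_p))
  }
  invisible(x)
}
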