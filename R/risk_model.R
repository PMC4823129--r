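# The 19 binary clinicopathological and marker factors screened for
# association with lymph node metastasis, in their conventional order.
.FACTORS <- c(
  "age_gt_51", "gender_female", "hbsag_pos", "hcv_ab_pos", "afp_gt_20",
  "alt_gt_40", "ggt_gt_50", "cirrhosis", "child_pugh_b",
  "differentiation_iii_iv", "size_gt_5cm", "multiple_tumors",
  "no_encapsulation", "vascular_invasion", "bclc_b_c",
  "mir_145_pos", "mir_31_pos", "mir_92a_pos", "mir_10b_high"
)

#' Names of the candidate risk factors
#'
#' The 19 binary clinicopathological and miRNA-marker covariates screened
#' for association with lymph node metastasis: age > 51 y, female gender,
#' HBsAg positivity, HCV antibody positivity, AFP > 20 ng/ml, ALT > 40 U/l,
#' gamma-GT > 50 U/l, liver cirrhosis, Child-Pugh class B, Edmondson grade
#' III--IV, tumor size > 5 cm, multiple tumors, absent encapsulation,
#' vascular invasion, BCLC stage B--C, and positivity/high expression of
#' miR-145, miR-31, miR-92a and miR-10b.
#'
#' @return Character vector of 19 factor names.
#' @export
candidate_factors <- function() .FACTORS

.check_cohort <- function(patients, factors = NULL) {
  if (!is.data.frame(patients) || nrow(patients) == 0L) {
    stop("patients must be a non-empty data frame", call. = FALSE)
  }
  need <- c("time_months", "event", factors)
  miss <- setdiff(need, names(patients))
  if (length(miss)) {
    stop("patient table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(patients$time_months)) || any(patients$time_months <= 0)) {
    stop("time_months must be finite and > 0", call. = FALSE)
  }
  if (!all(patients$event %in% c(0, 1))) {
    stop("event must be coded 0/1", call. = FALSE)
  }
  for (f in factors) {
    if (!all(patients[[f]] %in% c(0, 1))) {
      stop("factor '", f, "' must be coded 0/1", call. = FALSE)
    }
  }
  invisible(patients)
}

#' Cross-tabulate a binary factor against the metastasis event flag
#'
#' Builds the 2x2 table (factor absent/present by event no/yes) whose cells
#' are `a` = absent & no event, `b` = absent & event, `c` = present & no
#' event, `d` = present & event.
#'
#' @param patients Patient data frame with 0/1 factor columns and an
#'   `event` column.
#' @param factor Name of the factor column.
#' @return Named integer vector `c(a, b, c, d)`.
#' @export
contingency_from_cohort <- function(patients, factor) {
  .check_cohort(patients, factor)
  x <- patients[[factor]]
  y <- patients$event
  c(a = sum(x == 0 & y == 0), b = sum(x == 0 & y == 1),
    c = sum(x == 1 & y == 0), d = sum(x == 1 & y == 1))
}

#' Test a 2x2 factor-by-event table for association
#'
#' Uses Pearson's chi-square test (without continuity correction) when all
#' expected cell counts are at least 5, and otherwise falls back to the
#' two-sided Fisher exact test; the statistic reported is the chi-square or
#' the conditional odds-ratio estimate, respectively.
#'
#' @param tab Counts `c(a, b, c, d)` as produced by
#'   [contingency_from_cohort()], or a 2x2 matrix.
#' @param expected_min Expected-count threshold routing to Fisher's exact
#'   test, default 5.
#' @return List with `statistic`, `p_value` and `method`
#'   (`"chi-square"` or `"fisher"`).
#' @export
association_test <- function(tab, expected_min = 5) {
  if (!is.matrix(tab)) tab <- matrix(as.numeric(tab), 2, 2, byrow = TRUE)
  if (any(tab < 0) || sum(tab) <= 0) stop("invalid 2x2 table", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("degenerate table with a zero margin; no association testable")
    return(list(statistic = 0, p_value = 1, method = "chi-square"))
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (all(expected >= expected_min)) {
    ct <- stats::chisq.test(tab, correct = FALSE)
    list(statistic = unname(ct$statistic), p_value = ct$p.value,
         method = "chi-square")
  } else {
    ft <- stats::fisher.test(tab)
    list(statistic = unname(ft$estimate), p_value = ft$p.value,
         method = "fisher")
  }
}

# Fit a Cox model and capture survival's monotone-likelihood warnings so
# complete separation is surfaced as a flag rather than a hidden warning.
.coxph_flagged <- function(formula, data, ties) {
  flagged <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(formula, data = data, ties = ties),
    warning = function(w) {
      if (grepl("infinite|did not converge|beta may be", conditionMessage(w))) {
        flagged <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  list(fit = fit, separation = flagged)
}

#' Univariate proportional-hazards screen of one factor
#'
#' Fits a single-covariate Cox model of time to lymph node metastasis on a
#' binary factor and reports the hazard ratio with its Wald 95% confidence
#' interval and p-value.
#'
#' @param patients Patient data frame (`time_months`, `event`, factor
#'   columns).
#' @param factor Factor column name.
#' @param ties Tie-handling method passed to [survival::coxph()], default
#'   `"efron"`.
#' @return List with `factor`, `beta`, `se`, `hazard_ratio`, `ci95`,
#'   `p_value`, `method = "univariate-PH"`, and a logical `separation` flag
#'   (monotone likelihood: the hazard ratio estimate is effectively
#'   infinite and carried as `Inf`).
#' @export
univariate_ph <- function(patients, factor, ties = "efron") {
  .check_cohort(patients, factor)
  if (sum(patients$event) == 0) stop("no events in cohort", call. = FALSE)
  if (length(unique(patients[[factor]])) < 2L) {
    stop("factor '", factor, "' is constant across the cohort",
         call. = FALSE)
  }
  fml <- stats::as.formula(
    paste0("survival::Surv(time_months, event) ~ ", factor))
  res <- .coxph_flagged(fml, patients, ties)
  s <- summary(res$fit)
  beta <- unname(stats::coef(res$fit)[1L])
  se <- s$coefficients[1L, "se(coef)"]
  hr <- exp(beta)
  ci <- c(exp(beta - 1.959964 * se), exp(beta + 1.959964 * se))
  if (res$separation) {
    warning("monotone likelihood for factor '", factor,
            "': hazard ratio effectively infinite")
    hr <- if (beta > 0) Inf else 0
  }
  list(factor = factor, beta = beta, se = se, hazard_ratio = hr,
       ci95 = ci, p_value = s$coefficients[1L, "Pr(>|z|)"],
       method = "univariate-PH", separation = res$separation)
}

#' Univariate screening of candidate factors
#'
#' Runs [univariate_ph()] on each factor and retains those with two-sided
#' Wald p-value below `alpha`, preserving the input order.  Factors whose
#' fit fails (e.g. a constant column) are skipped with a warning.
#'
#' @param patients Patient data frame.
#' @param factors Character vector of factor column names, default all 19
#'   candidates.
#' @param alpha Two-sided significance level, default 0.05.
#' @param ties Cox tie-handling method.
#' @return Character vector of significant factor names.  The per-factor
#'   results are attached as attribute `"results"` (a data frame).
#' @export
screen_factors <- function(patients, factors = candidate_factors(),
                           alpha = 0.05, ties = "efron") {
  if (length(factors) == 0L) stop("factors must be non-empty", call. = FALSE)
  rows <- lapply(factors, function(f) {
    r <- tryCatch(univariate_ph(patients, f, ties = ties), error = function(e) {
      warning("skipping factor '", f, "': ", conditionMessage(e))
      NULL
    })
    if (is.null(r)) return(NULL)
    data.frame(factor = f, hazard_ratio = r$hazard_ratio,
               ci_low = r$ci95[1], ci_high = r$ci95[2],
               p_value = r$p_value, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  keep <- if (is.null(tab)) character(0) else
    tab$factor[!is.na(tab$p_value) & tab$p_value < alpha]
  structure(keep, results = tab)
}

#' Multivariate proportional-hazards fit with per-covariate Wald chi-square
#'
#' Jointly fits the screened factors in a Cox model by partial-likelihood
#' maximization and reports, per covariate, the log-hazard coefficient, its
#' standard error, the Wald chi-square `(beta/se)^2`, the hazard ratio with
#' Wald 95% CI, and the p-value from the chi-square(1) reference.
#'
#' @param patients Patient data frame.
#' @param factors Factor column names; a single factor reduces to the
#'   univariate fit.
#' @param ties Cox tie-handling method, default `"efron"`.
#' @return Data frame with one row per factor: `factor`, `beta`, `se`,
#'   `wald_chi2`, `hazard_ratio`, `ci_low`, `ci_high`, `p_value`.
#' @export
fit_multivariate_ph <- function(patients, factors, ties = "efron") {
  if (length(factors) < 1L) stop("need at least one factor", call. = FALSE)
  .check_cohort(patients, factors)
  if (sum(patients$event) < length(factors)) {
    stop("fewer events than covariates", call. = FALSE)
  }
  X <- as.matrix(patients[factors])
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1L) {
    dropped <- factors[qrX$pivot[-seq_len(qrX$rank)] - 1L]
    stop("collinear factor(s): ", paste(dropped, collapse = ", "),
         call. = FALSE)
  }
  fml <- stats::as.formula(paste0("survival::Surv(time_months, event) ~ ",
                                  paste(factors, collapse = " + ")))
  res <- .coxph_flagged(fml, patients, ties)
  fit <- res$fit
  if (!is.null(fit$info) && isTRUE(fit$info > 0)) {
    stop("Cox fit did not converge after ", fit$iter, " iterations",
         call. = FALSE)
  }
  beta <- stats::coef(fit)
  if (any(is.na(beta))) {
    stop("collinear factor(s): ",
         paste(names(beta)[is.na(beta)], collapse = ", "), call. = FALSE)
  }
  se <- sqrt(diag(stats::vcov(fit)))
  chi2 <- (beta / se)^2
  out <- data.frame(
    factor = factors, beta = unname(beta), se = unname(se),
    wald_chi2 = unname(chi2), hazard_ratio = unname(exp(beta)),
    ci_low = unname(exp(beta - 1.959964 * se)),
    ci_high = unname(exp(beta + 1.959964 * se)),
    p_value = unname(stats::pchisq(chi2, df = 1, lower.tail = FALSE)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# Round half away from zero to one decimal (2.594 -> 2.6, 1.665 -> 1.7);
# base round() would round half to even.
.round1_half_up <- function(x) sign(x) * floor(abs(x) * 10 + 0.5) / 10

#' Derive score weights from multivariate Wald chi-square statistics
#'
#' Each covariate's Wald chi-square is divided by the smallest chi-square in
#' the model and rounded half-away-from-zero to one decimal place, so the
#' weakest retained factor always carries weight 1.0 and each weight states
#' a factor's contribution relative to it.
#'
#' @param results Data frame from [fit_multivariate_ph()], or any data frame
#'   with columns `factor` and `wald_chi2`.
#' @return Object of class `score_table`: a list with `weights` (named
#'   numeric, one decimal) and `reference_chi2` (the minimum chi-square).
#' @export
#' @examples
#' res <- data.frame(
#'   factor = c("vascular_invasion", "bclc_b_c", "mir_145_pos",
#'              "mir_31_pos", "mir_92a_pos"),
#'   wald_chi2 = c(11.665, 5.632, 6.011, 7.485, 4.496))
#' derive_weights(res)
derive_weights <- function(results) {
  if (!is.data.frame(results) || nrow(results) == 0L) {
    stop("results must be a non-empty data frame", call. = FALSE)
  }
  chi2 <- results$wald_chi2
  if (any(!is.finite(chi2)) || any(chi2 <= 0)) {
    stop("all wald_chi2 values must be finite and > 0", call. = FALSE)
  }
  ref <- min(chi2)
  w <- .round1_half_up(chi2 / ref)
  structure(list(weights = stats::setNames(w, results$factor),
                 reference_chi2 = ref),
            class = "score_table")
}

#' @export
print.score_table <- function(x, ...) {
  cat("Risk score weights (per-factor Wald chi2 / minimum chi2 =",
      format(x$reference_chi2), "):\n")
  print(x$weights)
  cat("Maximum attainable total score:", sum(x$weights), "\n")
  invisible(x)
}

#' Total risk score of one or more patients
#'
#' Sums the score-table weights over the factors each patient carries.
#'
#' @param patients Patient data frame containing all factors named in the
#'   score table (a single patient is a one-row data frame).
#' @param table A `score_table` from [derive_weights()].
#' @return Numeric vector of total scores, one per patient row.
#' @export
total_score <- function(patients, table) {
  stopifnot(inherits(table, "score_table"))
  fac <- names(table$weights)
  miss <- setdiff(fac, names(patients))
  if (length(miss)) {
    stop("patient table lacks factor(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  as.numeric(as.matrix(patients[fac]) %*% table$weights)
}

# Pearson chi-square of a 2x2 table by the closed form
# n (ad - bc)^2 / (r1 r2 c1 c2); 0 when a margin vanishes.
.chi2_2x2 <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  den <- (a + b) * (c + d) * (a + c) * (b + d)
  if (den == 0) return(0)
  n * (a * d - b * c)^2 / den
}

#' Select the score cutoff maximizing risk-group separation
#'
#' Candidate cutoffs are the midpoints between consecutive distinct attained
#' scores.  For each candidate, patients are split into score > cutoff vs
#' score <= cutoff, and the Pearson chi-square of the resulting 2x2 split
#' against the event indicator is computed; the candidate with the largest
#' chi-square wins, ties resolved toward the smaller cutoff.  The
#' Cochran--Armitage chi-square for linear trend in event proportion across
#' all distinct score levels is reported alongside as a diagnostic.
#'
#' @param scores Numeric total scores.
#' @param outcomes 0/1 event indicators, same length.
#' @return List with `cutoff`, `chi2_at_cutoff`, `trend_statistic`
#'   (Cochran--Armitage over score categories), `trend_p`, and the
#'   `candidates` data frame (`cutoff`, `chi2`).
#' @export
select_cutoff <- function(scores, outcomes) {
  if (length(scores) != length(outcomes)) {
    stop("scores and outcomes differ in length", call. = FALSE)
  }
  if (!all(outcomes %in% c(0, 1))) stop("outcomes must be 0/1", call. = FALSE)
  lev <- sort(unique(scores))
  # collapse floating-point near-duplicates (total scores are sums of
  # one-decimal weights, so distinct levels differ by at least ~0.1)
  if (length(lev) > 1L) lev <- lev[c(TRUE, diff(lev) > 1e-8)]
  if (length(lev) < 2L) stop("all scores identical", call. = FALSE)
  if (length(unique(outcomes)) < 2L) {
    stop("all outcomes identical", call. = FALSE)
  }
  bin <- vapply(scores, function(s) which.min(abs(lev - s)), integer(1))
  cand <- (lev[-length(lev)] + lev[-1L]) / 2
  chi2 <- vapply(cand, function(cut) {
    hi <- scores > cut
    .chi2_2x2(sum(!hi & outcomes == 0), sum(!hi & outcomes == 1),
              sum(hi & outcomes == 0), sum(hi & outcomes == 1))
  }, numeric(1))
  best <- which.max(chi2)   # which.max takes the first (smallest) maximizer
  ev <- vapply(seq_along(lev), function(i) sum(outcomes[bin == i]),
               numeric(1))
  nn <- vapply(seq_along(lev), function(i) sum(bin == i), numeric(1))
  tr <- suppressWarnings(stats::prop.trend.test(ev, nn, score = lev))
  list(cutoff = cand[best], chi2_at_cutoff = chi2[best],
       trend_statistic = unname(tr$statistic), trend_p = tr$p.value,
       candidates = data.frame(cutoff = cand, chi2 = chi2))
}

#' Build the full risk model from a training cohort
#'
#' Runs the complete construction pipeline: univariate screening of the
#' candidate factors, multivariate Cox fit of the survivors, weight
#' derivation from the per-covariate Wald chi-squares, per-patient total
#' scores, and cutoff selection.
#'
#' @param patients Training cohort data frame.
#' @param factors Candidate factors, default all 19.
#' @param alpha Screening significance level, default 0.05.
#' @param ties Cox tie-handling method, default `"efron"`.
#' @return Object of class `lnm_model`: list with `score_table`, `cutoff`,
#'   `chi2_at_cutoff`, `trend_statistic`, `selected_factors`,
#'   `univariate` (screen table), `multivariate` (Cox table).
#' @export
build_risk_model <- function(patients, factors = candidate_factors(),
                             alpha = 0.05, ties = "efron") {
  sig <- screen_factors(patients, factors, alpha = alpha, ties = ties)
  if (length(sig) < 2L) {
    stop("fewer than two factors pass univariate screening", call. = FALSE)
  }
  mv <- fit_multivariate_ph(patients, sig, ties = ties)
  st <- derive_weights(mv)
  sc <- total_score(patients, st)
  cut <- select_cutoff(sc, patients$event)
  structure(list(score_table = st, cutoff = cut$cutoff,
                 chi2_at_cutoff = cut$chi2_at_cutoff,
                 trend_statistic = cut$trend_statistic,
                 selected_factors = sig,
                 univariate = attr(sig, "results"),
                 multivariate = mv),
            class = "lnm_model")
}

#' @export
print.lnm_model <- function(x, ...) {
  cat("Lymph-node-metastasis risk model\n")
  print(x$score_table)
  cat("Cutoff (score > cutoff = high risk):", x$cutoff,
      " [2x2 chi2 =", format(x$chi2_at_cutoff, digits = 4), "]\n")
  invisible(x)
}
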