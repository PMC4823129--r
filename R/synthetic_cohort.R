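# Default factor prevalences: training-cohort marginal frequencies of the
# 19 candidate factors (counts out of 192).
.DEFAULT_PREVALENCES <- c(
  age_gt_51 = 98, gender_female = 24, hbsag_pos = 139, hcv_ab_pos = 4,
  afp_gt_20 = 143, alt_gt_40 = 80, ggt_gt_50 = 123, cirrhosis = 161,
  child_pugh_b = 2, differentiation_iii_iv = 52, size_gt_5cm = 94,
  multiple_tumors = 53, no_encapsulation = 94, vascular_invasion = 27,
  bclc_b_c = 23, mir_145_pos = 47, mir_31_pos = 35, mir_92a_pos = 55,
  mir_10b_high = 59) / 192

# The five factors carried by the risk model, with the log hazard effects
# used as simulation truth (log of the multivariate hazard ratios).
.MODEL_FACTORS <- c("vascular_invasion", "bclc_b_c", "mir_145_pos",
                    "mir_31_pos", "mir_92a_pos")
.DEFAULT_EFFECTS <- stats::setNames(
  log(c(5.151, 2.899, 3.630, 3.506, 3.449)), .MODEL_FACTORS)

#' Specification of a synthetic survival cohort
#'
#' Bundles the parameters of the cohort simulator: marginal prevalences of
#' the binary factors, a latent Gaussian-copula correlation matrix coupling
#' them, per-factor log hazard effects, a constant baseline hazard, and a
#' uniform censoring (administrative follow-up) window.
#'
#' Defaults emulate the study design the package models: 19 factors at
#' their training-cohort prevalences, log-hazard effects equal to the log
#' multivariate hazard ratios of the five model factors (5.151, 2.899,
#' 3.630, 3.506, 3.449) and zero elsewhere, latent correlation 0.4 among
#' the five model factors (they co-occur in practice; the magnitude is an
#' assumption, not an estimate), follow-up uniform over 36--126 months, and
#' baseline hazard 1.6e-4 events/month, calibrated so that about 12% of
#' patients develop lymph node metastasis before censoring.
#'
#' @param n Cohort size.
#' @param factor_prevalences Named vector of marginal prevalences in (0,1).
#' @param latent_correlation Correlation matrix (or a single off-diagonal
#'   value applied among the five model factors); must be positive
#'   semi-definite with unit diagonal.
#' @param log_hazard_effects Named vector of log hazard ratios; factors not
#'   named get effect 0.
#' @param baseline_hazard Constant baseline hazard, events/month.
#' @param censoring_window Length-2 vector, uniform censoring bounds in
#'   months.
#' @param seed Integer RNG seed.
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 192,
                        factor_prevalences = .DEFAULT_PREVALENCES,
                        latent_correlation = 0.4,
                        log_hazard_effects = .DEFAULT_EFFECTS,
                        baseline_hazard = 1.6e-4,
                        censoring_window = c(36, 126),
                        seed = 1L) {
  if (n < 2) stop("n must be at least 2", call. = FALSE)
  p <- factor_prevalences
  if (is.null(names(p)) || any(names(p) == "")) {
    stop("factor_prevalences must be a fully named vector", call. = FALSE)
  }
  if (any(p <= 0 | p >= 1)) {
    stop("prevalences must lie strictly in (0, 1)", call. = FALSE)
  }
  k <- length(p)
  R <- latent_correlation
  if (is.matrix(R)) {
    if (!isTRUE(all.equal(dim(R), c(k, k))) ||
        !isTRUE(all.equal(diag(R), rep(1, k)))) {
      stop("latent_correlation matrix must be ", k, "x", k,
           " with unit diagonal", call. = FALSE)
    }
  } else {
    rho <- R
    R <- diag(k)
    idx <- match(intersect(.MODEL_FACTORS, names(p)), names(p))
    R[idx, idx] <- rho
    diag(R) <- 1
  }
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    stop("latent_correlation is not positive semi-definite", call. = FALSE)
  }
  dimnames(R) <- list(names(p), names(p))
  eff <- stats::setNames(rep(0, k), names(p))
  eff[names(log_hazard_effects)] <- log_hazard_effects
  if (baseline_hazard <= 0) stop("baseline_hazard must be > 0", call. = FALSE)
  if (length(censoring_window) != 2L ||
      censoring_window[1] <= 0 || diff(censoring_window) <= 0) {
    stop("censoring_window must be increasing positive bounds", call. = FALSE)
  }
  structure(list(n = as.integer(n), factor_prevalences = p,
                 latent_correlation = R, log_hazard_effects = eff,
                 baseline_hazard = baseline_hazard,
                 censoring_window = censoring_window,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic patient cohort
#'
#' Draws correlated binary factors by thresholding a multivariate normal at
#' the prevalence quantiles (Gaussian copula), then simulates time to lymph
#' node metastasis as exponential with rate
#' `baseline_hazard * exp(sum(effects * factors))` under uniform
#' administrative censoring.
#'
#' @param spec A [cohort_spec()].
#' @param cohort_label Value for the `cohort` column, default `"training"`.
#' @return Data frame with `patient_id`, one 0/1 column per factor,
#'   `time_months`, `event` and `cohort`.
#' @export
#' @examples
#' co <- generate_cohort(cohort_spec(n = 100, seed = 42))
#' mean(co$event)
generate_cohort <- function(spec, cohort_label = "training") {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  p <- spec$factor_prevalences
  k <- length(p)
  Z <- MASS::mvrnorm(spec$n, mu = rep(0, k), Sigma = spec$latent_correlation)
  X <- sweep(Z, 2L, stats::qnorm(p), "<") * 1L
  colnames(X) <- names(p)
  rate <- spec$baseline_hazard * exp(as.vector(X %*% spec$log_hazard_effects))
  t_event <- stats::rexp(spec$n, rate)
  t_cens <- stats::runif(spec$n, spec$censoring_window[1],
                         spec$censoring_window[2])
  out <- data.frame(
    patient_id = sprintf("%s-%04d", substr(cohort_label, 1, 1),
                         seq_len(spec$n)),
    X,
    time_months = pmin(t_event, t_cens),
    event = as.integer(t_event <= t_cens),
    cohort = cohort_label,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Generate a training/validation cohort pair of the study's design
#'
#' Produces two independent cohorts of 192 (training) and 209 (validation)
#' patients from the default [cohort_spec()], with sub-seeds derived from
#' `seed`.  Expected metastasis count is about 23 per cohort.
#'
#' @param seed Integer seed.
#' @return List with elements `training` and `validation`.
#' @export
generate_paperlike_pair <- function(seed = 1L) {
  set.seed(seed)
  sub <- sample.int(.Machine$integer.max - 1L, 2L)
  list(
    training = generate_cohort(cohort_spec(n = 192, seed = sub[1]),
                               cohort_label = "training"),
    validation = generate_cohort(cohort_spec(n = 209, seed = sub[2]),
                                 cohort_label = "validation"))
}

# Grid cells of the additive scoring system, split by a score threshold.
.additive_cells <- function() {
  g <- expand.grid(intensity = 0:3, percentage_category = 0:2)
  g$score <- g$intensity + g$percentage_category
  g
}

#' Emit synthetic two-rater ISH readings consistent with a cohort's calls
#'
#' Constructs, for each patient and each of the four markers, per-rater raw
#' readings whose scored calls reproduce the patient's ground-truth marker
#' status in the cohort table.  Positive miR-145 patients are emitted as
#' the unique positive cell (intensity 3, percentage 2); positive miR-31
#' as one of the three cells scoring above 3; miR-92a as intensity 1--3 vs
#' 0; miR-10b as percent stained above vs below 20.  Optional rater
#' disagreement perturbs the second rater's intensity by one step; calls
#' that flip under the perturbation are counted and reported in a message.
#'
#' @param cohort Data frame with columns `patient_id`, `mir_145_pos`,
#'   `mir_31_pos`, `mir_92a_pos`, `mir_10b_high`.
#' @param seed Integer seed.
#' @param rater_disagreement Probability that rater B's intensity differs
#'   by one step from rater A's, default 0 (exact agreement).
#' @return Readings data frame (`patient_id`, `core_id`, `marker`,
#'   `rater_id`, `intensity`, `percentage_category`, `percent_stained`)
#'   suitable for [score_markers()].
#' @export
generate_ish_readings <- function(cohort, seed = 1L,
                                  rater_disagreement = 0) {
  need <- c("patient_id", "mir_145_pos", "mir_31_pos", "mir_92a_pos",
            "mir_10b_high")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) {
    stop("cohort lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  set.seed(seed)
  cells <- .additive_cells()
  pick <- function(sub) sub[sample.int(nrow(sub), 1L), ]
  one <- function(pid, marker, truth) {
    base <- switch(marker,
      "miR-145" = {
        sub <- if (truth) cells[cells$score > 4, ] else cells[cells$score <= 4, ]
        pick(sub)
      },
      "miR-31" = {
        sub <- if (truth) cells[cells$score > 3, ] else cells[cells$score <= 3, ]
        pick(sub)
      },
      "miR-92a" = data.frame(intensity = if (truth) sample(1:3, 1) else 0,
                             percentage_category = NA_integer_),
      "miR-10b" = data.frame(intensity = NA_integer_,
                             percentage_category = NA_integer_,
                             percent_stained = if (truth)
                               stats::runif(1, 20, 100) else
                               stats::runif(1, 0, 19.99))
    )
    if (is.null(base$percent_stained)) base$percent_stained <- NA_real_
    raters <- rbind(base, base)
    if (rater_disagreement > 0 && !is.na(base$intensity[1]) &&
        stats::runif(1) < rater_disagreement) {
      step <- sample(c(-1L, 1L), 1L)
      raters$intensity[2] <- min(3L, max(0L, base$intensity[1] + step))
    }
    data.frame(patient_id = pid, core_id = "1", marker = marker,
               rater_id = c("A", "B"),
               intensity = raters$intensity,
               percentage_category = raters$percentage_category,
               percent_stained = raters$percent_stained,
               stringsAsFactors = FALSE)
  }
  truth_cols <- c("miR-145" = "mir_145_pos", "miR-31" = "mir_31_pos",
                  "miR-92a" = "mir_92a_pos", "miR-10b" = "mir_10b_high")
  out <- do.call(rbind, lapply(seq_len(nrow(cohort)), function(i) {
    do.call(rbind, lapply(names(truth_cols), function(m) {
      one(cohort$patient_id[i], m, cohort[[truth_cols[m]]][i] == 1)
    }))
  }))
  rownames(out) <- NULL
  if (rater_disagreement > 0) {
    calls <- score_markers(out, quiet = TRUE)
    truth <- unlist(lapply(names(truth_cols), function(m) {
      stats::setNames(cohort[[truth_cols[m]]],
                      paste(cohort$patient_id, m))
    }))
    got <- as.integer(calls$call %in% c("positive", "high"))
    names(got) <- paste(calls$patient_id, calls$marker)
    flips <- sum(got != truth[names(got)])
    message("rater disagreement flipped ", flips, " of ", length(got),
            " marker calls")
  }
  out
}
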