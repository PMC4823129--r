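# Shared fixture builders, all generated in code.

# Two-group exponential survival cohort: group 1 has `ratio` times the
# hazard of group 0.  No censoring unless cens_upper is finite.
two_group_cohort <- function(n, ratio, base_rate = 0.05,
                             cens_upper = Inf, seed = 1) {
  set.seed(seed)
  g <- rbinom(n, 1, 0.5)
  t_ev <- rexp(n, base_rate * ratio^g)
  t_c <- if (is.finite(cens_upper)) runif(n, 0, cens_upper) else Inf
  data.frame(g = g,
             time_months = pmin(t_ev, t_c),
             event = as.integer(t_ev <= t_c))
}

# A cohort with exact 2x2 cell counts for one factor:
# a = absent/no-event, b = absent/event, c = present/no-event,
# d = present/event.  Times are arbitrary positive values.
cohort_from_cells <- function(a, b, c, d, factor = "f") {
  x <- c(rep(0, a + b), rep(1, c + d))
  e <- c(rep(0, a), rep(1, b), rep(0, c), rep(1, d))
  out <- data.frame(x = x, time_months = seq_along(x) + 0.5, event = e)
  names(out)[1] <- factor
  out
}

# Independent oracle: two-sided Fisher exact p by exhaustive hypergeometric
# enumeration over all tables with the observed margins.
fisher_p_enum <- function(a, b, c, d) {
  m <- a + b          # row 1 total
  n2 <- c + d         # row 2 total
  k <- a + c          # column 1 total
  lo <- max(0, k - n2); hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n2, k)
  p_obs <- dhyper(a, m, n2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Independent oracle: AUC by the O(n^2) pairwise count with half credit
# for ties.
auc_pairwise <- function(scores, status) {
  cases <- scores[status == 1]; controls <- scores[status == 0]
  tot <- 0
  for (x in cases) for (y in controls) {
    tot <- tot + (x > y) + 0.5 * (x == y)
  }
  tot / (length(cases) * length(controls))
}

# Independent oracle: two-group log-rank chi-square, U^2/V with
# U = sum over event times of (O1 - E1) and V the hypergeometric variance.
logrank_oracle <- function(time, event, group) {
  ts <- sort(unique(time[event == 1]))
  U <- 0; V <- 0
  for (t in ts) {
    at <- time >= t
    n <- sum(at); n1 <- sum(at & group == 1)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & group == 1)
    U <- U + d1 - d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  U^2 / V
}

# Independent oracle: best midpoint cutoff by an exhaustive scan.
cutoff_scan_oracle <- function(scores, outcomes) {
  lev <- sort(unique(scores))
  cand <- (lev[-length(lev)] + lev[-1]) / 2
  best <- -Inf; best_cut <- NA
  for (cut in cand) {
    hi <- scores > cut
    tab <- matrix(c(sum(!hi & !outcomes), sum(!hi & outcomes),
                    sum(hi & !outcomes), sum(hi & outcomes)), 2, byrow = TRUE)
    n <- sum(tab)
    den <- prod(rowSums(tab)) * prod(colSums(tab))
    chi <- if (den == 0) 0 else
      n * (tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1])^2 / den
    if (chi > best + 1e-12) { best <- chi; best_cut <- cut }
  }
  list(cutoff = best_cut, chi2 = best)
}

# The Wald chi-square values of the five-factor multivariate fit used as
# the worked example throughout (vascular invasion, BCLC stage, miR-145,
# miR-31, miR-92a), and the weights they imply.
example_chi2 <- function() {
  data.frame(
    factor = c("vascular_invasion", "bclc_b_c", "mir_145_pos",
               "mir_31_pos", "mir_92a_pos"),
    wald_chi2 = c(11.665, 5.632, 6.011, 7.485, 4.496),
    stringsAsFactors = FALSE)
}
example_weights <- function() {
  c(vascular_invasion = 2.6, bclc_b_c = 1.3, mir_145_pos = 1.3,
    mir_31_pos = 1.7, mir_92a_pos = 1.0)
}
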