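test_that("contingency tables materialize factor-by-event counts", {
  co <- cohort_from_cells(154, 11, 15, 12, factor = "vascular_invasion")
  expect_identical(contingency_from_cohort(co, "vascular_invasion"),
                   c(a = 154L, b = 11L, c = 15L, d = 12L))
  expect_error(contingency_from_cohort(co, "nonexistent"), "lacks")
  expect_error(contingency_from_cohort(co[0, ], "vascular_invasion"),
               "non-empty")
  none <- cohort_from_cells(8, 0, 0, 0)
  expect_identical(contingency_from_cohort(none, "f"),
                   c(a = 8L, b = 0L, c = 0L, d = 0L))
})

test_that("association test matches the closed-form 2x2 chi-square identity", {
  # strongly associated table: chi2 by hand is n(ad-bc)^2/(r1 r2 c1 c2)
  res <- suppressWarnings(
    association_test(c(154, 11, 15, 12), expected_min = 0))
  hand <- 192 * (154 * 12 - 11 * 15)^2 / (165 * 27 * 169 * 23)
  expect_equal(res$statistic, hand)
  expect_identical(res$method, "chi-square")
  expect_lt(res$p_value, 0.001)
  # under the default routing this table (smallest expected cell 3.2)
  # falls to Fisher's exact test, with the same conclusion
  resf <- association_test(c(154, 11, 15, 12))
  expect_identical(resf$method, "fisher")
  expect_lt(resf$p_value, 0.001)

  bal <- association_test(c(10, 10, 10, 10))
  expect_equal(bal$statistic, 0)
  expect_equal(bal$p_value, 1)

  set.seed(42)
  for (i in 1:1000) {
    tab <- matrix(rpois(4, 40) + 5, 2)
    res <- association_test(tab)
    if (res$method != "chi-square") next
    a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
    n <- a + b + c + d
    expect_equal(res$statistic,
                 n * (a * d - b * c)^2 /
                   ((a + b) * (c + d) * (a + c) * (b + d)))
  }
})

test_that("sparse tables route to Fisher and match hypergeometric enumeration", {
  set.seed(99)
  n_fisher <- 0
  for (i in 1:200) {
    tab <- matrix(rpois(4, 3), 2)
    if (sum(tab) == 0 || any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    res <- suppressWarnings(association_test(tab))
    if (res$method != "fisher") next
    n_fisher <- n_fisher + 1
    expect_equal(res$p_value,
                 fisher_p_enum(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]),
                 tolerance = 1e-8)
  }
  expect_gt(n_fisher, 50)
  expect_warning(res0 <- association_test(c(5, 0, 7, 0)), "zero margin")
  expect_equal(res0$p_value, 1)
})

test_that("univariate PH fit recovers a known rate ratio and rejects degenerate input", {
  co <- two_group_cohort(500, ratio = 5, seed = 20)
  r <- univariate_ph(co, "g")
  expect_gt(r$hazard_ratio, 4)
  expect_lt(r$hazard_ratio, 6.25)
  expect_equal(r$hazard_ratio, exp(r$beta))
  expect_true(r$ci95[1] <= r$hazard_ratio && r$hazard_ratio <= r$ci95[2])

  # exchangeable groups: same event times in both arms -> beta near 0
  null <- two_group_cohort(400, ratio = 1, seed = 21)
  rn <- univariate_ph(null, "g")
  expect_lt(abs(rn$beta), 0.35)

  const <- data.frame(g = rep(1, 10), time_months = 1:10,
                      event = rep(c(0, 1), 5))
  expect_error(univariate_ph(const, "g"), "constant")
  noev <- data.frame(g = rep(0:1, 5), time_months = 1:10, event = 0)
  expect_error(univariate_ph(noev, "g"), "no events")
})

test_that("complete separation is flagged with an infinite hazard-ratio sentinel", {
  co <- data.frame(g = rep(c(0, 1), each = 20),
                   time_months = c(runif(20, 50, 100), runif(20, 1, 5)),
                   event = rep(c(0, 1), each = 20))
  expect_warning(r <- univariate_ph(co, "g"), "monotone likelihood")
  expect_true(r$separation)
  expect_identical(r$hazard_ratio, Inf)
})

test_that("screening keeps factors below alpha, in input order, skipping failures", {
  set.seed(8)
  co <- generate_cohort(cohort_spec(n = 600, seed = 8))
  all_kept <- suppressWarnings(screen_factors(co, alpha = 1))
  # alpha = 1 retains every factor that could be fitted, in input order
  expect_identical(as.character(all_kept),
                   intersect(candidate_factors(), as.character(all_kept)))
  expect_gt(length(all_kept), 15)
  expect_length(suppressWarnings(screen_factors(co, alpha = 0)), 0)
  res <- attr(suppressWarnings(screen_factors(co)), "results")
  expect_true(all(c("factor", "hazard_ratio", "p_value") %in% names(res)))
  # a constant column is skipped with a warning, not fatal
  co$constant <- 1
  expect_warning(screen_factors(co, factors = c("vascular_invasion", "constant"),
                                alpha = 1),
                 "skipping factor 'constant'")
})

test_that("multivariate fit reports Wald chi-squares consistent with beta/se and flags collinearity", {
  set.seed(31)
  co <- generate_cohort(cohort_spec(n = 1500, seed = 31))
  five <- c("vascular_invasion", "bclc_b_c", "mir_145_pos", "mir_31_pos",
            "mir_92a_pos")
  mv <- fit_multivariate_ph(co, five)
  expect_identical(mv$factor, five)
  expect_equal(mv$wald_chi2, (mv$beta / mv$se)^2)
  expect_equal(mv$hazard_ratio, exp(mv$beta))
  expect_equal(mv$p_value, pchisq(mv$wald_chi2, 1, lower.tail = FALSE))
  expect_true(all(mv$ci_low <= mv$hazard_ratio & mv$hazard_ratio <= mv$ci_high))

  co$dup <- co$vascular_invasion
  expect_error(fit_multivariate_ph(co, c(five, "dup")), "collinear")

  # a single covariate reduces exactly to the univariate fit
  uni <- univariate_ph(co, "mir_31_pos")
  one <- fit_multivariate_ph(co, "mir_31_pos")
  expect_equal(one$beta, uni$beta, tolerance = 1e-8)
  expect_equal(one$se, uni$se, tolerance = 1e-8)
})

test_that("null covariates rarely reach large Wald chi-squares", {
  set.seed(55)
  q99 <- qchisq(0.99, 1)
  below <- 0; total <- 0
  for (i in 1:60) {
    co <- data.frame(f1 = rbinom(150, 1, 0.4), f2 = rbinom(150, 1, 0.3),
                     time_months = rexp(150, 0.02),
                     event = rbinom(150, 1, 0.4))
    if (sum(co$event) < 2) next
    mv <- tryCatch(fit_multivariate_ph(co, c("f1", "f2")),
                   error = function(e) NULL)
    if (is.null(mv)) next
    total <- total + 2
    below <- below + sum(mv$wald_chi2 < q99)
  }
  expect_gt(below / total, 0.95)
})

test_that("weight derivation divides by the minimum chi-square and rounds half up to one decimal", {
  st <- derive_weights(example_chi2())
  expect_equal(st$weights, example_weights())
  expect_equal(st$reference_chi2, 4.496)
  expect_equal(min(st$weights), 1.0)

  one <- derive_weights(data.frame(factor = "f", wald_chi2 = 7.3))
  expect_equal(unname(one$weights), 1.0)
  two <- derive_weights(data.frame(factor = c("a", "b"),
                                   wald_chi2 = c(8.992, 4.496)))
  expect_equal(unname(two$weights), c(2.0, 1.0))

  # scale invariance: multiplying all chi-squares by k > 0 changes nothing
  for (k in c(0.25, 3, 117)) {
    ex <- example_chi2(); ex$wald_chi2 <- ex$wald_chi2 * k
    expect_equal(derive_weights(ex)$weights, example_weights())
  }
  expect_error(derive_weights(example_chi2()[0, ]), "non-empty")
  bad <- example_chi2(); bad$wald_chi2[1] <- 0
  expect_error(derive_weights(bad), "> 0")
})

test_that("total scores sum carried weights, monotonically in added factors", {
  st <- derive_weights(example_chi2())
  all_pos <- as.data.frame(as.list(setNames(rep(1, 5), names(st$weights))))
  expect_equal(total_score(all_pos, st), 7.9)
  expect_equal(round(total_score(all_pos, st)), 8)
  all_neg <- all_pos; all_neg[1, ] <- 0
  expect_equal(total_score(all_neg, st), 0)
  only31 <- all_neg; only31$mir_31_pos <- 1
  expect_equal(total_score(only31, st), 1.7)
  # monotone: switching any factor on never decreases the score
  for (f in names(st$weights)) {
    plus <- all_neg; plus[[f]] <- 1
    expect_gte(total_score(plus, st), total_score(all_neg, st))
  }
  expect_error(total_score(all_pos[-1], st), "lacks factor")
})

test_that("cutoff selection maximizes the 2x2 chi-square over attained-score midpoints", {
  sc <- c(0, 0, 1.7, 5.6, 5.6, 7.9)
  ev <- c(0, 0, 0, 1, 1, 1)
  res <- select_cutoff(sc, ev)
  expect_gt(res$cutoff, 1.7)
  expect_lt(res$cutoff, 5.6)
  expect_equal(res$cutoff, (1.7 + 5.6) / 2)

  set.seed(12)
  for (i in 1:25) {
    s <- sample(seq(0, 8, by = 0.5), 40, replace = TRUE)
    e <- rbinom(40, 1, plogis((s - 4) / 2))
    if (length(unique(e)) < 2 || length(unique(s)) < 2) next
    got <- select_cutoff(s, e)
    want <- cutoff_scan_oracle(s, e)
    expect_equal(got$cutoff, want$cutoff)
    expect_equal(got$chi2_at_cutoff, want$chi2)
    # permutation invariance
    p <- sample(40)
    expect_equal(select_cutoff(s[p], e[p])$cutoff, got$cutoff)
  }
  expect_error(select_cutoff(rep(1, 5), c(0, 1, 0, 1, 0)), "identical")
  expect_error(select_cutoff(1:5, rep(1, 5)), "identical")
})

test_that("the full build pipeline returns a coherent model object", {
  co <- generate_cohort(cohort_spec(n = 2000, seed = 77))
  m <- suppressWarnings(build_risk_model(co))
  expect_s3_class(m, "lnm_model")
  expect_equal(min(m$score_table$weights), 1.0)
  rng <- range(total_score(co, m$score_table))
  expect_gt(m$cutoff, rng[1])
  expect_lt(m$cutoff, rng[2])
  expect_true(all(m$selected_factors %in% candidate_factors()))
  expect_output(print(m), "Cutoff")
})
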