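test_that("chi-square reproduces published statistics from rebuilt counts", {
  # sex by frailty: 63.2% of 239 men and 44.5% of 497 women frail,
  # margin-checked against the 372 frail subjects
  sex_tab <- reconstruct_counts(c(63.2, 44.5), c(239, 497),
                                trait_total = 372)
  expect_equal(unname(sex_tab[, "yes"]), c(151, 221))
  r <- pearson_chi2(sex_tab)
  expect_equal(r$statistic, 22.6, tolerance = 0.005)
  expect_equal(r$df, 1)
  expect_lt(r$p, 0.001)

  # respiratory disease by vital status: 12.3% of 342 alive, 17.8% of 394
  # dead
  resp_tab <- reconstruct_counts(c(12.3, 17.8), c(342, 394))
  expect_equal(unname(resp_tab[, "yes"]), c(42, 70))
  expect_equal(pearson_chi2(resp_tab)$statistic, 4.27, tolerance = 0.005)

  # a margin mismatch is surfaced, not silently used
  expect_warning(reconstruct_counts(c(63.2, 44.5), c(239, 497),
                                    trait_total = 370), "margin")
})

test_that("chi-square equals the direct formula and respects symmetry", {
  direct_chi2 <- function(m) {
    e <- outer(rowSums(m), colSums(m)) / sum(m)
    sum((m - e)^2 / e)
  }
  set.seed(120)
  for (i in 1:50) {
    m <- matrix(stats::rbinom(4, 200, 0.4) + 1L, 2)
    r <- pearson_chi2(m)
    expect_equal(r$statistic, direct_chi2(m), tolerance = 1e-10)
    # invariance to transposition and to swapping both labels
    expect_equal(pearson_chi2(t(m))$statistic, r$statistic)
    expect_equal(pearson_chi2(m[2:1, 2:1])$statistic, r$statistic)
    # identity with the squared two-proportion z statistic
    n1 <- sum(m[1, ]); n2 <- sum(m[2, ])
    p1 <- m[1, 1] / n1; p2 <- m[2, 1] / n2
    pp <- (m[1, 1] + m[2, 1]) / (n1 + n2)
    z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
    expect_equal(r$statistic, z^2, tolerance = 1e-10)
  }
  expect_equal(pearson_chi2(matrix(10, 2, 2))$statistic, 0)
  # Yates correction only ever shrinks the statistic
  m <- matrix(c(20, 10, 8, 25), 2)
  expect_lt(pearson_chi2(m, continuity_correction = TRUE)$statistic,
            pearson_chi2(m)$statistic)
  expect_error(pearson_chi2(matrix(c(0, 0, 5, 5), 2)), "margin")
})

test_that("summary-statistics t-test matches the closed form and raw data", {
  # group summaries as printed for FI by sex and age by vital status
  r1 <- two_sample_t_from_summary(0.24, 0.10, 239, 0.20, 0.10, 497)
  expect_equal(r1$t, 0.04 / (0.10 * sqrt(1 / 239 + 1 / 497)),
               tolerance = 1e-10)
  expect_equal(r1$t, 5.08, tolerance = 0.001)
  expect_equal(r1$df, 734)

  r2 <- two_sample_t_from_summary(93.9, 3.4, 394, 93.3, 3.4, 342)
  expect_equal(r2$t, 2.39, tolerance = 0.005)

  expect_equal(two_sample_t_from_summary(5, 1, 30, 5, 1, 30)$t, 0)
  expect_error(two_sample_t_from_summary(2, 0, 10, 2, 0, 10), "undefined")

  # summaries computed from raw data reproduce the raw-data pooled t-test
  set.seed(130)
  a <- stats::rnorm(40, 1, 2); b <- stats::rnorm(55, 0.5, 2)
  rs <- two_sample_t_from_summary(mean(a), stats::sd(a), length(a),
                                  mean(b), stats::sd(b), length(b))
  tt <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(rs$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(rs$p, tt$p.value, tolerance = 1e-12)
  # Welch option matches t.test's default too
  rw <- two_sample_t_from_summary(mean(a), stats::sd(a), length(a),
                                  mean(b), stats::sd(b), length(b),
                                  pooled = FALSE)
  tw <- stats::t.test(a, b)
  expect_equal(rw$t, unname(tw$statistic), tolerance = 1e-12)
  expect_equal(rw$df, unname(tw$parameter), tolerance = 1e-9)
})

test_that("proportion intervals reproduce the published prevalence CI", {
  wilson <- proportion_ci(372, 736)
  expect_equal(round(100 * wilson[["lower"]], 1), 46.9)
  expect_equal(round(100 * wilson[["upper"]], 1), 54.1)
  # agreement with the score-test inversion in stats::prop.test
  pt <- stats::prop.test(372, 736, correct = FALSE)$conf.int
  expect_equal(unname(wilson), as.numeric(pt), tolerance = 1e-10)

  wald <- proportion_ci(50, 100, method = "wald")
  expect_equal(unname(wald), c(0.402, 0.598), tolerance = 1e-3)
  # degenerate Wald at k = 0 collapses to a point
  expect_equal(unname(proportion_ci(0, 10, method = "wald")), c(0, 0))

  # Wilson always contains k/n
  set.seed(140)
  for (i in 1:100) {
    n <- sample(1:500, 1); k <- sample(0:n, 1)
    ci <- proportion_ci(k, n)
    expect_true(ci[["lower"]] <= k / n && k / n <= ci[["upper"]])
  }
  expect_error(proportion_ci(1, 0), "n")
})

test_that("group tables assemble t-tests and chi-squares per variable", {
  cohort <- make_toy_cohort(n = 400, seed = 150)
  scores <- score_cohort(cohort)
  cohort$frail <- scores$frail
  cohort$fi <- scores$fi

  tab <- build_group_table(cohort, "frail")
  expect_true(all(c("variable", "type", "statistic", "p", "flag")
                  %in% names(tab)))
  expect_true("age" %in% tab$variable)
  expect_true(all(tab$type %in% c("continuous", "categorical")))
  # fi differs by construction between frail groups: strongest signal
  expect_lt(tab$p[tab$variable == "fi"], 1e-10)

  # a covariate that copies the grouping is flagged as perfectly associated
  cohort$copy <- as.integer(cohort$frail)
  tab2 <- build_group_table(cohort, "frail", categorical = "copy")
  expect_lt(tab2$p[tab2$variable == "copy"], 1e-12)
  expect_equal(tab2$flag[tab2$variable == "copy"], "**")

  cohort$one <- TRUE
  expect_error(build_group_table(cohort, "one"), "2 levels")

  # vital-status grouping works off the event flag
  tab3 <- build_group_table(cohort, "event")
  expect_true(nrow(tab3) >= 3)
})
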