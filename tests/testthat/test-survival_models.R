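test_that("Cox coefficient matches a grid-search Breslow oracle", {
  # four subjects, all events, alternating exposure: the exposed subjects
  # die first and third, so the partial likelihood has a finite interior
  # maximiser that both routes must find
  toy <- data.frame(time = c(1, 2, 3, 4), event = 1L,
                    x = c(1, 0, 1, 0))
  fit <- fit_cox(toy, "x")
  oracle <- grid_search_cox(toy$time, toy$event, toy$x)
  expect_equal(unname(fit$coef), oracle, tolerance = 1e-4)
  # the reported optimum beats nearby perturbations (local optimality)
  ll_at <- function(b) breslow_loglik(b, toy$time, toy$event, toy$x)
  expect_gte(ll_at(unname(fit$coef)) + 1e-10, ll_at(unname(fit$coef) + 0.01))
  expect_gte(ll_at(unname(fit$coef)) + 1e-10, ll_at(unname(fit$coef) - 0.01))
  # and the model's own log partial likelihood agrees with the oracle's
  expect_equal(fit$log_partial_likelihood, ll_at(unname(fit$coef)),
               tolerance = 1e-8)
})

test_that("Cox oracle agreement holds on larger tie-free data too", {
  set.seed(81)
  n <- 60
  x <- rep(0:1, each = n / 2)
  time <- stats::rexp(n, 0.2 * exp(0.5 * x))
  event <- as.integer(time <= 3)
  d <- data.frame(time = pmin(time, 3), event = event, x = x)
  fit <- fit_cox(d, "x")
  expect_equal(unname(fit$coef), grid_search_cox(d$time, d$event, d$x),
               tolerance = 1e-4)
  # sign of the coefficient matches the concordance direction
  expect_gt(unname(fit$coef), 0)
})

test_that("a null exposure yields HR near 1 with nominal CI behaviour", {
  set.seed(82)
  n <- 4000
  d <- data.frame(time = pmin(stats::rexp(n, 0.3), 4),
                  x = stats::rbinom(n, 1, 0.5))
  d$event <- as.integer(d$time < 4)
  fit <- fit_cox(d, "x")
  expect_equal(unname(fit$hazard_ratios), 1, tolerance = 0.12)
  expect_true(fit$ci_lower <= fit$ci_upper)
})

test_that("degenerate designs are rejected with clear errors", {
  d <- data.frame(time = 1:4, event = c(1L, 1L, 0L, 1L), x = c(1, 1, 1, 1))
  expect_error(fit_cox(d, "x"), "constant")
  d2 <- data.frame(time = 1:4, event = 0L, x = c(0, 1, 0, 1))
  expect_error(fit_cox(d2, "x"), "events")
  expect_error(fit_cox(d, "missing_col"), "lacks")
})

test_that("per-variable screen is consistent and flags unstable cells", {
  cohort <- make_toy_cohort(n = 300, seed = 91)
  scores <- score_cohort(cohort)
  cohort$frail <- scores$frail
  codes <- code_cohort(cohort)

  # a deficit column identical to the frail flag reproduces fit_cox
  codes2 <- cbind(codes, frail_copy = as.integer(cohort$frail))
  screen <- per_variable_hr_screen(cohort, codes2)
  ref <- fit_cox(cohort, "frail")
  row <- screen[screen$variable == "frail_copy", ]
  expect_equal(row$hr, unname(ref$hazard_ratios), tolerance = 1e-10)
  expect_equal(row$ci_lower, unname(ref$ci_lower), tolerance = 1e-10)

  # a variable with a single deficit subject cannot meet the
  # events-per-arm threshold and is withheld
  rare <- c(1L, rep(0L, nrow(cohort) - 1L))
  screen2 <- per_variable_hr_screen(cohort, cbind(codes, rare = rare))
  row2 <- screen2[screen2$variable == "rare", ]
  expect_false(row2$stable)
  expect_true(is.na(row2$hr))

  # constant columns are not estimable
  screen3 <- per_variable_hr_screen(cohort,
                                    cbind(codes, allzero = 0L))
  expect_false(screen3$estimable[screen3$variable == "allzero"])
})

test_that("Nelson-Aalen estimator matches hand computation", {
  d <- data.frame(time = c(1, 2, 3), event = 1L, g = "all")
  curve <- nelson_aalen_curve(d, "g")
  expect_equal(curve$cumhaz, c(0, 1 / 3, 1 / 3 + 1 / 2, 1 / 3 + 1 / 2 + 1),
               tolerance = 1e-12)
  expect_equal(curve$time, c(0, 1, 2, 3))
  # starts at zero, non-decreasing step function
  expect_true(all(diff(curve$cumhaz) >= 0))

  # duplicating every record leaves the estimator unchanged
  d2 <- rbind(d, d)
  curve2 <- nelson_aalen_curve(d2, "g")
  expect_equal(curve2$cumhaz, curve$cumhaz, tolerance = 1e-12)
  expect_equal(curve2$time, curve$time)

  expect_error(nelson_aalen_curve(data.frame(time = 1, event = 0L,
                                             g = "a"), "g"),
               "at least one event")
})

test_that("grouped cumulative-hazard curves separate under a true effect", {
  cohort <- make_toy_cohort(n = 736, seed = 95)
  scores <- score_cohort(cohort)
  cohort$frail <- ifelse(scores$frail, "frail", "non-frail")
  curves <- nelson_aalen_curve(cohort, "frail")
  expect_setequal(unique(curves$group), c("frail", "non-frail"))
  for (g in unique(curves$group)) {
    cc <- curves[curves$group == g, ]
    expect_equal(cc$cumhaz[1], 0)
    expect_true(all(diff(cc$cumhaz) >= 0))
  }
  # under hr > 1 the frail curve should end higher
  end <- vapply(c("frail", "non-frail"), function(g)
    max(curves$cumhaz[curves$group == g]), numeric(1))
  expect_gt(end[["frail"]], end[["non-frail"]])
})

test_that("adjusted models with independent covariates barely move the HR", {
  ratios <- vapply(c(201L, 202L, 203L), function(s) {
    cohort <- generate_cohort(sim_config(), seed = s)
    scores <- score_cohort(cohort)
    cohort$frail <- scores$frail
    tab <- frailty_model_table(cohort)
    max(abs(log(tab$hr / tab$hr[tab$model == "unadjusted"])))
  }, numeric(1))
  expect_lt(max(ratios), 0.08)
})

test_that("the recovery experiment is unbiased at the null", {
  cfg <- sim_config(n_subjects = 300, hr_frail = 1.0)
  rec <- recovery_experiment(cfg, n_reps = 40, seed = 101)
  expect_lt(abs(rec$bias_log_hr), 3 * rec$se_log_hr + 1e-12)
  # nominal 95% coverage within binomial noise at 40 replicates
  expect_gt(rec$coverage, 0.80)
})
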