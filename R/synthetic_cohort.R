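#' Intraclass correlation matching a target FI spread
#'
#' For exchangeable Bernoulli deficits with success probability `p` and
#' pairwise intraclass correlation `rho`, the variance of the per-subject
#' deficit mean over an `n_vars` panel is
#' `p (1 - p) [1 + (n_vars - 1) rho] / n_vars`. This solves that identity
#' for `rho` given a target standard deviation of the index.
#'
#' When some panel variables are missing completely at random, the observed
#' index `k_obs / n_obs` keeps mean `p` but spreads slightly more, since
#' `Var = p(1-p)[rho + (1-rho) E(1/n_obs)]` and `E(1/n_obs) > 1/n_vars`.
#' Passing `missing_rate > 0` solves the identity with `n_obs ~
#' Binomial(n_vars, 1 - missing_rate)` so the realised index still hits the
#' target SD.
#'
#' @param p Per-variable deficit probability (mean FI target).
#' @param sd_target Target standard deviation of the index.
#' @param n_vars Panel size.
#' @param missing_rate Completely-at-random per-variable missingness the
#'   index will be computed under (0 = complete panel, the plain identity).
#' @return The intraclass correlation (may be negative if the target SD is
#'   below the independence value `sqrt(p(1-p)/n_vars)`; an error if >= 1).
#' @examples
#' icc_from_moments(0.21, 0.10, 22)  # ~0.0155
#' @export
icc_from_moments <- function(p, sd_target, n_vars, missing_rate = 0) {
  stopifnot(p > 0, p < 1, sd_target >= 0, n_vars >= 2,
            missing_rate >= 0, missing_rate < 1)
  if (missing_rate == 0) {
    e_inv <- 1 / n_vars
  } else {
    # E[1/n_obs] over n_obs ~ Binom(n_vars, 1 - missing_rate), n_obs >= 1
    k <- 1:n_vars
    pk <- stats::dbinom(k, n_vars, 1 - missing_rate)
    e_inv <- sum(pk / k) / sum(pk)
  }
  rho <- (sd_target^2 / (p * (1 - p)) - e_inv) / (1 - e_inv)
  if (rho >= 1) stop("target SD unattainable: implied ICC >= 1")
  rho
}

#' Simulation configuration for a synthetic nonagenarian cohort
#'
#' Defaults emulate the published study conditions: 736 community-dwelling
#' subjects aged 90-108 (mean 93.6, SD 3.4), 67.5% women, a 22-variable lab
#' panel whose deficit structure is calibrated so the frailty index has mean
#' 0.21 and SD 0.10, frailty classified at the 0.21 cut-point, a frail
#' vs non-frail mortality hazard ratio of 1.32, and an overall 4-year death
#' proportion of 53.5% under administrative censoring at 4 years.
#'
#' @param n_subjects Cohort size.
#' @param deficit_mean Per-variable deficit probability (target mean FI).
#' @param fi_sd Target SD of the index; the deficit intraclass correlation
#'   is solved from it via [icc_from_moments()].
#' @param deficit_icc Explicit intraclass correlation; overrides `fi_sd`.
#' @param panel Reference panel (defines panel size and lab realisation).
#' @param prop_female Probability a subject is female.
#' @param age_mean,age_sd,age_range Age distribution (truncated normal),
#'   years.
#' @param hr_frail True mortality hazard ratio of frail vs non-frail.
#' @param target_mortality Overall death proportion at the end of follow-up.
#' @param followup_years Administrative censoring time, years.
#' @param missing_rate Completely-at-random lab missingness probability.
#' @param cutpoint,completeness_threshold Scoring parameters used to define
#'   the frailty flag that drives survival.
#' @param covariate_prevalences Named probabilities for the binary lifestyle
#'   and chronic-disease covariates.
#' @param education_probs Probabilities for the three education levels
#'   (illiterate, primary, secondary or above).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 736,
                       deficit_mean = 0.21,
                       fi_sd = 0.10,
                       deficit_icc = NULL,
                       panel = load_reference_panel(),
                       prop_female = 0.675,
                       age_mean = 93.6, age_sd = 3.4,
                       age_range = c(90, 108),
                       hr_frail = 1.32,
                       target_mortality = 0.535,
                       followup_years = 4,
                       missing_rate = 0.02,
                       cutpoint = 0.21,
                       completeness_threshold = 0.70,
                       covariate_prevalences = c(
                         smoking = 0.434, alcohol = 0.258, exercise = 0.386,
                         hypertension = 0.101, cardiovascular = 0.048,
                         cerebrovascular = 0.020, diabetes = 0.009,
                         respiratory = 0.152, digestive = 0.172,
                         renal = 0.024, osteoarthritis = 0.293),
                       education_probs = c(illiterate = 0.723,
                                           primary = 0.252,
                                           secondary_plus = 0.025)) {
  n_vars <- length(panel_variables(panel))
  if (is.null(deficit_icc))
    deficit_icc <- icc_from_moments(deficit_mean, fi_sd, n_vars,
                                    missing_rate = missing_rate)
  stopifnot(n_subjects >= 1,
            deficit_mean > 0, deficit_mean < 1,
            deficit_icc >= 0, deficit_icc < 1,
            prop_female >= 0, prop_female <= 1,
            hr_frail > 0,
            target_mortality > 0, target_mortality < 1,
            followup_years > 0,
            missing_rate >= 0, missing_rate < 1,
            diff(age_range) > 0,
            all(covariate_prevalences >= 0 & covariate_prevalences <= 1),
            abs(sum(education_probs) - 1) < 1e-6)
  structure(list(n_subjects = n_subjects, deficit_mean = deficit_mean,
                 deficit_icc = deficit_icc, panel = panel,
                 n_vars = n_vars, prop_female = prop_female,
                 age_mean = age_mean, age_sd = age_sd,
                 age_range = age_range, hr_frail = hr_frail,
                 target_mortality = target_mortality,
                 followup_years = followup_years,
                 missing_rate = missing_rate, cutpoint = cutpoint,
                 completeness_threshold = completeness_threshold,
                 covariate_prevalences = covariate_prevalences,
                 education_probs = education_probs),
            class = "sim_config")
}

#' Draw a correlated binary deficit matrix
#'
#' Beta-Bernoulli (exchangeable) model: each subject gets a latent deficit
#' propensity `q_i ~ Beta(a, b)` with mean `p` and intraclass correlation
#' `icc = 1 / (a + b + 1)`, then `panel_size` independent Bernoulli(`q_i`)
#' indicators. `icc = 0` degenerates to independent Bernoulli(`p`).
#'
#' @param n Number of subjects (rows).
#' @param p Marginal deficit probability.
#' @param icc Intraclass correlation in \[0, 1).
#' @param panel_size Number of deficit indicators (columns).
#' @param seed Optional integer seed (local RNG stream).
#' @return Integer 0/1 matrix, `n` x `panel_size`.
#' @export
sample_deficit_matrix <- function(n, p, icc, panel_size, seed = NULL) {
  stopifnot(n >= 1, panel_size >= 1, p >= 0, p <= 1)
  if (icc >= 1 || icc < 0) stop("icc must lie in [0, 1)")
  if (icc > 0 && (p <= 0 || p >= 1))
    stop("p must be strictly inside (0, 1) when icc > 0")
  if (!is.null(seed)) {
    old <- .Random.seed_get()
    on.exit(.Random.seed_set(old), add = TRUE)
    set.seed(seed)
  }
  if (icc == 0) {
    q <- rep(p, n)
  } else {
    ab <- 1 / icc - 1
    q <- stats::rbeta(n, p * ab, (1 - p) * ab)
  }
  matrix(stats::rbinom(n * panel_size, 1L, rep(q, each = panel_size)),
         nrow = n, ncol = panel_size, byrow = TRUE)
}

# save/restore .Random.seed so seeded helpers do not disturb the caller's
# RNG stream
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Realise lab values consistent with a deficit matrix
#'
#' For each 0 code a value is drawn uniformly inside the subject's normal
#' range; for each 1 code a value is drawn outside it, choosing the low or
#' high side at random for two-sided ranges, within a bounded offset of the
#' violated bound. Re-coding the emitted values reproduces the input codes
#' exactly (draws are continuous, so boundary values occur with probability
#' zero, and R's uniform sampler never returns an interval endpoint).
#'
#' @param deficits 0/1 matrix from [sample_deficit_matrix()], columns in
#'   panel order.
#' @param sexes Character vector (`"male"`/`"female"`), one per row.
#' @param panel An `fi_panel`.
#' @param seed Optional integer seed.
#' @return Numeric matrix of lab values, same shape as `deficits`, columns
#'   named by panel variable.
#' @export
realise_lab_values <- function(deficits, sexes,
                               panel = load_reference_panel(),
                               seed = NULL) {
  vars <- panel_variables(panel)
  if (ncol(deficits) != length(vars))
    stop("deficit matrix has ", ncol(deficits), " columns; panel has ",
         length(vars), " variables")
  if (length(sexes) != nrow(deficits))
    stop("need one sex per deficit row")
  if (!is.null(seed)) {
    old <- .Random.seed_get()
    on.exit(.Random.seed_set(old), add = TRUE)
    set.seed(seed)
  }
  out <- matrix(NA_real_, nrow(deficits), length(vars),
                dimnames = list(rownames(deficits), vars))
  for (j in seq_along(vars)) {
    for (sx in c("male", "female")) {
      rows <- which(sexes == sx)
      if (!length(rows)) next
      rg <- panel_range(panel, vars[j], sx)
      out[rows, j] <- draw_lab_block(deficits[rows, j], rg)
    }
  }
  out
}

# vectorised draw for one (variable, sex) block; rg is a one-row range
draw_lab_block <- function(codes, rg) {
  n <- length(codes)
  val <- numeric(n)
  lo <- rg$lower; up <- rg$upper
  # offset scale for out-of-range / half-open draws
  span <- switch(rg$bound_style,
    interval   = up - lo,
    upper_only = max(up, 1),
    lower_only = max(lo, 1))
  normal <- codes == 0L
  if (any(normal)) {
    k <- sum(normal)
    val[normal] <- switch(rg$bound_style,
      interval   = stats::runif(k, lo, up),
      upper_only = stats::runif(k, max(0, up - span), up),
      lower_only = stats::runif(k, lo, lo + span))
  }
  if (any(!normal)) {
    k <- sum(!normal)
    val[!normal] <- switch(rg$bound_style,
      interval = {
        side_low <- stats::runif(k) < 0.5
        ifelse(side_low,
               stats::runif(k, lo - 0.25 * span, lo),
               stats::runif(k, up, up + 0.25 * span))
      },
      # deficit region is value >= up; runif excludes its left endpoint,
      # drawn values are > up and code back to 1
      upper_only = stats::runif(k, up, up + 0.25 * span),
      lower_only = stats::runif(k, max(0, lo - 0.25 * span), lo))
  }
  val
}

#' Calibrate the baseline hazard to a target overall mortality
#'
#' Under exponential event times within group, frail prevalence `prev` and
#' frail hazard ratio `hr`, the overall death proportion at follow-up `t` is
#' `1 - [(1 - prev) exp(-lambda t) + prev exp(-hr lambda t)]`. Solves for
#' the non-frail rate `lambda` by bracketed root-finding.
#'
#' @param target_mortality Overall death proportion in (0, 1).
#' @param prev_frail Frail prevalence in \[0, 1\].
#' @param hr Frail hazard ratio (> 0).
#' @param followup Follow-up length, years.
#' @return Baseline (non-frail) hazard rate per year; residual of the
#'   calibration identity below 1e-10.
#' @examples
#' calibrate_baseline_hazard(0.535, 0, 1, 4)    # -log(0.465)/4
#' calibrate_baseline_hazard(0.535, 0.505, 1.32, 4)  # ~0.166
#' @export
calibrate_baseline_hazard <- function(target_mortality, prev_frail, hr,
                                      followup) {
  stopifnot(target_mortality > 0, target_mortality < 1,
            prev_frail >= 0, prev_frail <= 1, hr > 0, followup > 0)
  surv_target <- 1 - target_mortality
  f <- function(l)
    (1 - prev_frail) * exp(-l * followup) +
      prev_frail * exp(-hr * l * followup) - surv_target
  hi <- 1
  while (f(hi) > 0 && hi < 1e6) hi <- hi * 2
  if (f(1e-12) < 0 || f(hi) > 0)
    stop("baseline-hazard calibration failed: no sign change in bracket")
  root <- stats::uniroot(f, c(1e-12, hi), tol = 1e-14)$root
  if (abs(f(root)) > 1e-10)
    stop("baseline-hazard calibration residual too large")
  root
}

#' Simulate proportional-hazards survival with administrative censoring
#'
#' Latent exponential event times with rate `baseline * hr` for frail
#' subjects and `baseline` otherwise; times beyond `followup` are censored
#' there with `event = 0`.
#'
#' @param frail_flags Logical vector.
#' @param baseline Non-frail hazard rate per year (> 0).
#' @param hr Frail hazard ratio.
#' @param followup Administrative censoring time, years.
#' @param seed Optional integer seed.
#' @return Data frame with `time` (years, in (0, followup\]) and `event`
#'   (1 = death).
#' @export
simulate_survival <- function(frail_flags, baseline, hr, followup,
                              seed = NULL) {
  stopifnot(baseline > 0, hr > 0, followup > 0)
  if (!is.null(seed)) {
    old <- .Random.seed_get()
    on.exit(.Random.seed_set(old), add = TRUE)
    set.seed(seed)
  }
  rate <- baseline * ifelse(frail_flags, hr, 1)
  latent <- stats::rexp(length(frail_flags), rate)
  data.frame(time = pmin(latent, followup),
             event = as.integer(latent <= followup))
}

#' Generate a full synthetic cohort
#'
#' Assembles demographics, correlated lab deficits realised as concrete lab
#' values, completely-at-random missingness, independent lifestyle and
#' chronic-disease covariates, and proportional-hazards survival. The
#' frailty flag driving survival is the one the scoring pipeline itself
#' produces (deficits scored at the configured cut-point), and the baseline
#' hazard is calibrated against that cohort's own frail prevalence so the
#' expected overall death proportion equals `target_mortality`.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; the run is fully reproducible given the seed.
#' @return Cohort data frame: `id`, `sex`, `age`, one column per panel
#'   variable, `education`, the binary covariates, `time`, `event`.
#'   Attributes `baseline_hazard`, `true_frail` and `seed` record the
#'   generating state.
#' @export
generate_cohort <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  n <- config$n_subjects

  sex <- ifelse(stats::runif(n) < config$prop_female, "female", "male")
  age <- rnorm_truncated(n, config$age_mean, config$age_sd,
                         config$age_range[1], config$age_range[2])

  deficits <- sample_deficit_matrix(n, config$deficit_mean,
                                    config$deficit_icc, config$n_vars)
  labs <- realise_lab_values(deficits, sex, config$panel)
  if (config$missing_rate > 0) {
    drop <- matrix(stats::runif(length(labs)) < config$missing_rate,
                   nrow = n)
    labs[drop] <- NA_real_
  }

  education <- sample(names(config$education_probs), n, replace = TRUE,
                      prob = config$education_probs)
  covs <- as.data.frame(lapply(config$covariate_prevalences, function(pr)
    stats::rbinom(n, 1L, pr)))

  # frailty as the scoring pipeline sees it, from the pre-missingness codes
  scored <- score_deficit_matrix(deficits,
                                 completeness_threshold =
                                   config$completeness_threshold,
                                 cutpoint = config$cutpoint)
  frail <- scored$frail
  prev <- mean(frail)
  baseline <- calibrate_baseline_hazard(config$target_mortality, prev,
                                        config$hr_frail,
                                        config$followup_years)
  surv <- simulate_survival(frail, baseline, config$hr_frail,
                            config$followup_years)

  cohort <- data.frame(id = sprintf("S%04d", seq_len(n)),
                       sex = sex, age = age,
                       as.data.frame(labs),
                       education = education,
                       covs,
                       time = surv$time, event = surv$event,
                       stringsAsFactors = FALSE)
  attr(cohort, "baseline_hazard") <- baseline
  attr(cohort, "true_frail") <- frail
  attr(cohort, "seed") <- seed
  cohort
}

# truncated-normal sampler by rejection; the [90, 108] default keeps ~85%
# acceptance, so vectorised resampling converges in a few passes
rnorm_truncated <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lo | x[bad] > hi]
  }
  x
}
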