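#' Covariate sets for the adjusted mortality models
#'
#' Nested adjustment sets: model 1 adds age, sex and education to the
#' unadjusted frailty model; model 2 adds the lifestyle factors (smoking,
#' alcohol, exercise); model 3 adds the eight chronic-disease indicators.
#'
#' @param set One of `"unadjusted"`, `"model1"`, `"model2"`, `"model3"`.
#' @return Character vector of covariate column names (possibly empty).
#' @export
model_covariates <- function(set = c("unadjusted", "model1", "model2",
                                     "model3")) {
  set <- match.arg(set)
  m1 <- c("age", "sex", "education")
  m2 <- c(m1, "smoking", "alcohol", "exercise")
  m3 <- c(m2, "hypertension", "cardiovascular", "cerebrovascular",
          "diabetes", "respiratory", "digestive", "renal", "osteoarthritis")
  switch(set, unadjusted = character(0), model1 = m1, model2 = m2,
         model3 = m3)
}

#' Fit a Cox proportional-hazards model for an exposure
#'
#' Maximum partial likelihood via [survival::coxph()], Breslow tie handling
#' by default. Hazard ratios are exponentiated coefficients with 95% Wald
#' confidence intervals on the log scale.
#'
#' @param cohort Data frame with `time` and `event` columns plus the
#'   exposure and covariates.
#' @param exposure Name of the exposure column (binary or numeric).
#' @param covariates Covariate column names, e.g. from [model_covariates()].
#' @param ties `"breslow"` (default) or `"efron"`.
#' @param conf_level Confidence level for the Wald intervals.
#' @return A list of class `filab_cox`: `term_names`, `hazard_ratios`,
#'   `ci_lower`, `ci_upper`, `coef`, `se`, `p`, `log_partial_likelihood`,
#'   `n`, `n_events`, `ties_method`, and the underlying `fit`.
#' @export
fit_cox <- function(cohort, exposure, covariates = character(0),
                    ties = c("breslow", "efron"), conf_level = 0.95) {
  ties <- match.arg(ties)
  need <- c("time", "event", exposure, covariates)
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop("cohort lacks columns: ", paste(miss, collapse = ", "))
  if (sum(cohort$event) < 1L) stop("no events in cohort")
  expo <- cohort[[exposure]]
  if (length(unique(expo[!is.na(expo)])) < 2L)
    stop("degenerate design: exposure '", exposure, "' is constant")

  rhs <- paste(c(exposure, covariates), collapse = " + ")
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~", rhs))
  fit <- survival::coxph(fml, data = cohort, ties = ties)
  if (!is.null(fit$info) && isTRUE(fit$info$convergence > 0))
    stop("Cox fit did not converge")
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(term_names = names(beta),
                 hazard_ratios = exp(beta),
                 ci_lower = exp(beta - z * se),
                 ci_upper = exp(beta + z * se),
                 coef = beta, se = se,
                 p = 2 * stats::pnorm(-abs(beta / se)),
                 log_partial_likelihood = fit$loglik[2L],
                 n = fit$n, n_events = fit$nevent,
                 ties_method = ties, fit = fit),
            class = "filab_cox")
}

#' @export
print.filab_cox <- function(x, ...) {
  cat("Cox proportional-hazards fit (", x$ties_method, " ties), ",
      x$n, " subjects, ", x$n_events, " events\n", sep = "")
  tab <- data.frame(term = x$term_names,
                    HR = round(x$hazard_ratios, 3),
                    lower95 = round(x$ci_lower, 3),
                    upper95 = round(x$ci_upper, 3),
                    p = signif(x$p, 3))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Fit the four frailty-mortality models
#'
#' Unadjusted plus the three nested adjusted models of [model_covariates()],
#' each with the frailty flag as exposure.
#'
#' @param cohort Cohort data frame including a logical/0-1 `frail` column
#'   (e.g. merged from [score_cohort()]).
#' @param ties Tie handling, see [fit_cox()].
#' @return Data frame with one row per model: model label, frailty HR, CI
#'   bounds, p-value, events.
#' @export
frailty_model_table <- function(cohort, ties = "breslow") {
  sets <- c("unadjusted", "model1", "model2", "model3")
  rows <- lapply(sets, function(s) {
    covs <- intersect(model_covariates(s), names(cohort))
    # drop covariates that are constant in this cohort (inestimable)
    covs <- covs[vapply(covs, function(cv)
      length(unique(cohort[[cv]])) > 1L, logical(1))]
    f <- fit_cox(cohort, "frail", covs, ties = ties)
    i <- grep("^frail", f$term_names)[1L]
    data.frame(model = s, hr = f$hazard_ratios[i],
               ci_lower = f$ci_lower[i], ci_upper = f$ci_upper[i],
               p = f$p[i], n_events = f$n_events,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-variable deficit hazard screen
#'
#' One univariate Cox fit per panel variable with that variable's deficit
#' code as the sole binary regressor. Variables with fewer than
#' `min_events_per_arm` deaths in either the deficit or the normal arm are
#' flagged unstable and their estimates withheld (`NA`), mirroring how
#' near-empty cells produce uninterpretable hazard ratios.
#'
#' @param cohort Cohort with `time` and `event`.
#' @param codes Deficit matrix from [code_cohort()], rows aligned with
#'   `cohort`.
#' @param min_events_per_arm Stability threshold (default 5).
#' @param ties Tie handling.
#' @return Data frame: variable, n_deficit, events in each arm, hr,
#'   ci_lower, ci_upper, p, estimable, stable.
#' @export
per_variable_hr_screen <- function(cohort, codes, min_events_per_arm = 5L,
                                   ties = "breslow") {
  stopifnot(nrow(codes) == nrow(cohort))
  rows <- lapply(colnames(codes), function(v) {
    code <- codes[, v]
    keep <- !is.na(code)
    sub <- cohort[keep, c("time", "event")]
    sub$deficit <- code[keep]
    n1 <- sum(sub$deficit == 1L)
    ev1 <- sum(sub$event[sub$deficit == 1L])
    ev0 <- sum(sub$event[sub$deficit == 0L])
    estimable <- n1 > 0L && n1 < nrow(sub) && (ev0 + ev1) > 0L
    stable <- estimable && ev0 >= min_events_per_arm &&
      ev1 >= min_events_per_arm
    if (stable) {
      f <- fit_cox(sub, "deficit", ties = ties)
      data.frame(variable = v, n_deficit = n1, events_deficit = ev1,
                 events_normal = ev0, hr = f$hazard_ratios[1L],
                 ci_lower = f$ci_lower[1L], ci_upper = f$ci_upper[1L],
                 p = f$p[1L], estimable = estimable, stable = stable,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(variable = v, n_deficit = n1, events_deficit = ev1,
                 events_normal = ev0, hr = NA_real_, ci_lower = NA_real_,
                 ci_upper = NA_real_, p = NA_real_, estimable = estimable,
                 stable = stable, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Nelson-Aalen cumulative-hazard curves by group
#'
#' Nonparametric cumulative hazard: at each distinct event time the
#' increment is (events at that time) / (subjects still at risk), summed
#' over time, computed per group via [survival::survfit()].
#'
#' @param cohort Cohort with `time` and `event`.
#' @param group Name of a grouping column, or a vector of group labels
#'   aligned with rows.
#' @return Data frame of step-function points: `group`, `time`, `cumhaz`,
#'   `n_risk`, `n_event` — each group's curve starts at (0, 0) and is
#'   non-decreasing.
#' @export
nelson_aalen_curve <- function(cohort, group = "frail") {
  g <- if (length(group) == 1L && is.character(group)) {
    if (!group %in% names(cohort))
      stop("grouping column '", group, "' not found")
    cohort[[group]]
  } else group
  if (length(g) != nrow(cohort)) stop("group labels must match cohort rows")
  if (anyNA(g)) {
    keep <- !is.na(g)
    cohort <- cohort[keep, , drop = FALSE]
    g <- g[keep]
  }
  lv <- unique(g)
  ev_per <- vapply(lv, function(l) sum(cohort$event[g == l]), numeric(1))
  if (any(ev_per < 1))
    stop("every group needs at least one event; none in: ",
         paste(lv[ev_per < 1], collapse = ", "))
  d <- data.frame(time = cohort$time, event = cohort$event, grp = g)
  sf <- survival::survfit(survival::Surv(time, event) ~ grp, data = d)
  strata_labels <- if (is.null(sf$strata)) {
    as.character(lv[1L])
  } else sub("^grp=", "", names(sf$strata))
  strata_sizes <- if (is.null(sf$strata)) length(sf$time) else sf$strata
  grp_of <- rep(strata_labels, strata_sizes)
  out <- data.frame(group = grp_of, time = sf$time, cumhaz = sf$cumhaz,
                    n_risk = sf$n.risk, n_event = sf$n.event,
                    stringsAsFactors = FALSE)
  origin <- data.frame(group = strata_labels,
                       time = 0, cumhaz = 0, n_risk = NA_integer_,
                       n_event = 0L, stringsAsFactors = FALSE)
  out <- rbind(origin, out)
  out[order(out$group, out$time), , drop = FALSE]
}

#' Plot cumulative-hazard curves
#'
#' Base-graphics step plot of [nelson_aalen_curve()] output.
#'
#' @param curves Data frame from [nelson_aalen_curve()].
#' @param main,xlab,ylab Plot annotation.
#' @param col Colours, recycled over groups.
#' @return Invisibly, the curve data.
#' @export
plot_cumhaz <- function(curves, main = "Cumulative hazard of death",
                        xlab = "Years of follow-up",
                        ylab = "Cumulative hazard",
                        col = c("#1b7837", "#b2182b", "#2166ac")) {
  groups <- unique(curves$group)
  col <- rep_len(col, length(groups))
  plot(NA, xlim = range(curves$time), ylim = range(curves$cumhaz),
       xlab = xlab, ylab = ylab, main = main)
  for (i in seq_along(groups)) {
    cc <- curves[curves$group == groups[i], ]
    graphics::lines(cc$time, cc$cumhaz, type = "s", col = col[i], lwd = 2)
  }
  graphics::legend("topleft", legend = groups, col = col, lwd = 2, bty = "n")
  invisible(curves)
}

#' Simulation-based parameter-recovery experiment
#'
#' Repeats generate -> score -> fit: each replicate draws a synthetic
#' cohort, scores it through the full lab-coding pipeline, fits the
#' unadjusted Cox model for frailty, and records the estimate. Summarises
#' the bias of the log hazard ratio and the empirical coverage of the
#' nominal 95% confidence intervals against the configured truth.
#'
#' @param config A [sim_config()]; `config$hr_frail` is the truth.
#' @param n_reps Number of replicates (>= 2).
#' @param seed Integer; replicate r uses seed `seed + r - 1`.
#' @return List: per-replicate `hr` and `covered`, plus `mean_hr`, `sd_hr`,
#'   `se_mean_hr`, `mean_log_hr`, `bias_log_hr`, `se_log_hr`, `coverage`,
#'   `true_hr`, `n_reps`.
#' @export
recovery_experiment <- function(config = sim_config(), n_reps = 200,
                                seed = 1L) {
  stopifnot(n_reps >= 2)
  true_log <- log(config$hr_frail)
  hr <- covered <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    cohort <- generate_cohort(config, seed = seed + r - 1L)
    scores <- score_cohort(cohort, config$panel,
                           config$completeness_threshold, config$cutpoint)
    cohort$frail <- scores$frail
    f <- fit_cox(cohort, "frail")
    hr[r] <- f$hazard_ratios[1L]
    covered[r] <- f$ci_lower[1L] <= config$hr_frail &&
      config$hr_frail <= f$ci_upper[1L]
  }
  log_hr <- log(hr)
  list(hr = hr, covered = as.logical(covered),
       mean_hr = mean(hr), sd_hr = stats::sd(hr),
       se_mean_hr = stats::sd(hr) / sqrt(n_reps),
       mean_log_hr = mean(log_hr),
       bias_log_hr = mean(log_hr) - true_log,
       se_log_hr = stats::sd(log_hr) / sqrt(n_reps),
       coverage = mean(covered),
       true_hr = config$hr_frail, n_reps = n_reps)
}
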