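#' Pearson chi-square test on a 2x2 contingency table
#'
#' The statistic is `sum (O - E)^2 / E` with expected counts from the
#' margins; with the Yates continuity correction enabled, 0.5 is subtracted
#' from each `|O - E|` first. Uncorrected is the default, matching the
#' common large-sample reporting convention for cohort tables.
#'
#' @param counts 2x2 non-negative integer matrix.
#' @param continuity_correction Apply the Yates correction?
#' @return List: `statistic`, `df` (1), `p`, `expected`.
#' @examples
#' pearson_chi2(matrix(c(151, 221, 88, 276), 2))$statistic  # ~22.6
#' @export
pearson_chi2 <- function(counts, continuity_correction = FALSE) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2L, 2L)))
    stop("counts must be a 2x2 matrix")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (sum(counts) < 1) stop("empty table")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero row or column margin: expected counts undefined")
  # the small-expected-count approximation warning is the caller's concern;
  # inputs are validated above and the statistic is exact either way
  ct <- suppressWarnings(
    stats::chisq.test(counts, correct = continuity_correction))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, expected = ct$expected)
}

#' Reconstruct 2x2 counts from printed percentages and margins
#'
#' Given the group sizes and the printed percentage of a trait in each
#' group, rounds `pct * n / 100` to the nearest integer and, when a trait
#' total is supplied, verifies the reconstruction against it.
#'
#' @param pct Length-2 percentages (one per group).
#' @param n Length-2 group sizes.
#' @param trait_total Optional known total with the trait, for verification.
#' @return 2x2 matrix, rows = groups, columns = trait yes/no.
#' @export
reconstruct_counts <- function(pct, n, trait_total = NULL) {
  stopifnot(length(pct) == 2L, length(n) == 2L)
  yes <- round(pct * n / 100)
  if (!is.null(trait_total) && sum(yes) != trait_total)
    warning("reconstructed trait total ", sum(yes),
            " differs from printed margin ", trait_total)
  matrix(c(yes, n - yes), nrow = 2L,
         dimnames = list(group = c("g1", "g2"), trait = c("yes", "no")))
}

#' Two-sample t-test from summary statistics
#'
#' Unpaired t-test computed from group means, SDs and sizes, as needed when
#' only published summaries are available. Pooled variance with
#' `df = n_a + n_b - 2` by default; Welch available. Sign convention is
#' `a - b`.
#'
#' @param mean_a,sd_a,n_a First group summary (n >= 2, sd >= 0).
#' @param mean_b,sd_b,n_b Second group summary.
#' @param pooled Pooled-variance t (default) or Welch.
#' @return List: `t`, `df`, `p` (two-sided).
#' @examples
#' two_sample_t_from_summary(0.24, 0.10, 239, 0.20, 0.10, 497)$t  # ~5.08
#' @export
two_sample_t_from_summary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b,
                                      pooled = TRUE) {
  stopifnot(n_a >= 2, n_b >= 2, sd_a >= 0, sd_b >= 0)
  if (sd_a == 0 && sd_b == 0 && mean_a == mean_b)
    stop("undefined t: both SDs zero with equal means")
  if (pooled) {
    sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / (n_a + n_b - 2)
    se <- sqrt(sp2 * (1 / n_a + 1 / n_b))
    df <- n_a + n_b - 2
  } else {
    va <- sd_a^2 / n_a
    vb <- sd_b^2 / n_b
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (n_a - 1) + vb^2 / (n_b - 1))
  }
  tt <- (mean_a - mean_b) / se
  list(t = tt, df = df, p = 2 * stats::pt(-abs(tt), df))
}

#' Confidence interval for a binomial proportion
#'
#' Wilson score interval by default (inverts the score test; always
#' contains `k/n` and needs no clipping); the simple Wald interval is
#' available and is clipped to \[0, 1\], which can leave it degenerate at
#' the boundaries (`k = 0` or `k = n`).
#'
#' @param k Number of successes.
#' @param n Number of trials (>= 1).
#' @param level Confidence level.
#' @param method `"wilson"` or `"wald"`.
#' @return Named vector `c(lower, upper)`.
#' @examples
#' proportion_ci(372, 736)  # ~(0.469, 0.541)
#' @export
proportion_ci <- function(k, n, level = 0.95, method = c("wilson", "wald")) {
  method <- match.arg(method)
  stopifnot(n >= 1, k >= 0, k <= n, level > 0, level < 1)
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- k / n
  if (method == "wilson") {
    denom <- 1 + z^2 / n
    centre <- (p + z^2 / (2 * n)) / denom
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
    ci <- c(centre - half, centre + half)
  } else {
    half <- z * sqrt(p * (1 - p) / n)
    ci <- c(p - half, p + half)
  }
  ci <- pmin(pmax(ci, 0), 1)
  stats::setNames(ci, c("lower", "upper"))
}

#' Build a Table-1/2-style group-comparison report
#'
#' Compares the two levels of a grouping variable over a set of continuous
#' and categorical columns: mean +/- SD with an unpaired pooled t-test for
#' continuous variables, percentage with an uncorrected chi-square test for
#' binary variables. Significance is flagged at 0.05 (`*`) and 0.01 (`**`).
#'
#' @param cohort Data frame.
#' @param grouping Name of a two-level grouping column (e.g. `"frail"` or
#'   `"event"`).
#' @param continuous,categorical Column names to compare; defaults pick the
#'   standard demographic/lifestyle sets present in the cohort.
#' @return Data frame: variable, type, per-group summary strings, test
#'   statistic, p, flag.
#' @export
build_group_table <- function(cohort, grouping,
                              continuous = NULL, categorical = NULL) {
  if (!grouping %in% names(cohort))
    stop("grouping column '", grouping, "' not found")
  g <- cohort[[grouping]]
  keep <- !is.na(g)
  cohort <- cohort[keep, , drop = FALSE]
  g <- g[keep]
  lv <- sort(unique(g))
  if (length(lv) != 2L)
    stop("grouping must have exactly 2 levels, found ", length(lv))
  if (is.null(continuous))
    continuous <- intersect(c("age", "fi"), names(cohort))
  if (is.null(categorical))
    categorical <- intersect(c("sex", "smoking", "alcohol", "exercise",
                               "hypertension", "cardiovascular",
                               "cerebrovascular", "diabetes", "respiratory",
                               "digestive", "renal", "osteoarthritis",
                               "frail", "event"),
                             setdiff(names(cohort), grouping))
  a <- g == lv[1]
  b <- g == lv[2]
  rows <- list()
  for (v in continuous) {
    xa <- cohort[[v]][a]; xb <- cohort[[v]][b]
    xa <- xa[!is.na(xa)]; xb <- xb[!is.na(xb)]
    tt <- two_sample_t_from_summary(mean(xa), stats::sd(xa), length(xa),
                                    mean(xb), stats::sd(xb), length(xb))
    rows[[v]] <- data.frame(
      variable = v, type = "continuous",
      group_a = sprintf("%.2f ± %.2f", mean(xa), stats::sd(xa)),
      group_b = sprintf("%.2f ± %.2f", mean(xb), stats::sd(xb)),
      statistic = tt$t, p = tt$p, stringsAsFactors = FALSE)
  }
  for (v in categorical) {
    x <- cohort[[v]]
    pos <- if (is.logical(x)) x
           else if (is.numeric(x)) x == 1
           else x == sort(unique(x))[1]
    ka <- sum(pos[a], na.rm = TRUE); na <- sum(!is.na(pos[a]))
    kb <- sum(pos[b], na.rm = TRUE); nb <- sum(!is.na(pos[b]))
    tab <- matrix(c(ka, kb, na - ka, nb - kb), 2L)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      stat <- NA_real_; p <- NA_real_
    } else {
      cs <- pearson_chi2(tab)
      stat <- cs$statistic; p <- cs$p
    }
    rows[[v]] <- data.frame(
      variable = v, type = "categorical",
      group_a = sprintf("%.1f%%", 100 * ka / na),
      group_b = sprintf("%.1f%%", 100 * kb / nb),
      statistic = stat, p = p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$flag <- ifelse(is.na(out$p), "",
                     ifelse(out$p < 0.01, "**",
                            ifelse(out$p < 0.05, "*", "")))
  attr(out, "groups") <- stats::setNames(c(sum(a), sum(b)),
                                         as.character(lv))
  rownames(out) <- NULL
  out
}
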