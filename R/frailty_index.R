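#' Compute the FI-LAB frailty index for one deficit vector
#'
#' The index is the number of deficits divided by the number of panel
#' variables actually measured. A subject's index is valid only when at
#' least `completeness_threshold` of the panel is non-missing (default 70%);
#' otherwise `fi` is `NA` and no frailty classification is made.
#'
#' @param codes Integer vector of deficit codes (0/1/`NA`) over the panel,
#'   as from [code_subject()].
#' @param completeness_threshold Minimum non-missing fraction for a valid
#'   index, in (0, 1].
#' @param cutpoint Frailty cut-point passed to [classify_frailty()].
#' @return A list with `fi`, `n_deficits`, `n_considered`, `completeness`,
#'   `valid` and `frail`.
#' @examples
#' compute_fi(c(rep(1L, 11), rep(0L, 11)))$fi  # 0.5
#' @export
compute_fi <- function(codes, completeness_threshold = 0.70,
                       cutpoint = 0.21) {
  if (!length(codes)) stop("empty deficit vector")
  stopifnot(completeness_threshold > 0, completeness_threshold <= 1)
  n_panel <- length(codes)
  n_considered <- sum(!is.na(codes))
  n_deficits <- sum(codes, na.rm = TRUE)
  completeness <- n_considered / n_panel
  valid <- completeness >= completeness_threshold
  fi <- if (valid) n_deficits / n_considered else NA_real_
  list(fi = fi,
       n_deficits = as.integer(n_deficits),
       n_considered = as.integer(n_considered),
       completeness = completeness,
       valid = valid,
       frail = if (valid) classify_frailty(fi, cutpoint) else NA)
}

#' Classify frailty from an FI-LAB value
#'
#' Frail at or above the cut-point (the inclusive ">=" convention of the
#' published 0.21 cut-point).
#'
#' @param fi Frailty index in \[0, 1\] (vectorised).
#' @param cutpoint Cut-point in \[0, 1\]; 0.21 by default. Values in the
#'   0.20-0.25 band are conventional for comparability with phenotype-based
#'   frailty.
#' @return Logical vector, `NA` where `fi` is `NA`.
#' @export
classify_frailty <- function(fi, cutpoint = 0.21) {
  if (any(fi < 0 | fi > 1, na.rm = TRUE))
    stop("fi must lie in [0, 1]")
  stopifnot(cutpoint >= 0, cutpoint <= 1)
  fi >= cutpoint
}

#' Score a whole cohort
#'
#' Applies deficit coding and [compute_fi()] to every subject.
#'
#' @param cohort Cohort data frame (see [read_cohort()]).
#' @param panel An `fi_panel`.
#' @param completeness_threshold,cutpoint See [compute_fi()].
#' @return Data frame: `id`, `fi`, `n_deficits`, `n_considered`,
#'   `completeness`, `valid`, `frail` — one row per subject, cohort order.
#' @export
score_cohort <- function(cohort, panel = load_reference_panel(),
                         completeness_threshold = 0.70, cutpoint = 0.21) {
  codes <- code_cohort(cohort, panel)
  score_deficit_matrix(codes, id = cohort$id,
                       completeness_threshold = completeness_threshold,
                       cutpoint = cutpoint)
}

#' Score a precomputed deficit matrix
#'
#' @param codes Integer matrix of 0/1/`NA` codes, subjects x variables.
#' @param id Optional subject identifiers.
#' @param completeness_threshold,cutpoint See [compute_fi()].
#' @return Same layout as [score_cohort()].
#' @export
score_deficit_matrix <- function(codes, id = NULL,
                                 completeness_threshold = 0.70,
                                 cutpoint = 0.21) {
  if (is.null(id)) id <- seq_len(nrow(codes))
  n_panel <- ncol(codes)
  n_considered <- rowSums(!is.na(codes))
  n_deficits <- rowSums(codes == 1L, na.rm = TRUE)
  completeness <- n_considered / n_panel
  valid <- completeness >= completeness_threshold
  fi <- ifelse(valid, n_deficits / n_considered, NA_real_)
  data.frame(id = id, fi = fi,
             n_deficits = as.integer(n_deficits),
             n_considered = as.integer(n_considered),
             completeness = completeness,
             valid = valid,
             frail = ifelse(valid, fi >= cutpoint, NA),
             stringsAsFactors = FALSE)
}

#' Summarise the FI-LAB distribution of a scored cohort
#'
#' Moments and order statistics are taken over subjects with a valid index
#' only. Quantiles use linear interpolation between order statistics
#' (`stats::quantile` type 7); the standard deviation uses the n-1
#' denominator.
#'
#' @param scores Data frame from [score_cohort()] (needs `fi` and `valid`).
#' @param cutpoint Frailty cut-point for the prevalence figure.
#' @param ci_level Confidence level for the Wilson interval on prevalence.
#' @return A list with `n_valid`, `mean`, `sd`, `median`, `maximum`, `p99`,
#'   `n_frail`, `prevalence_frail` and `prevalence_ci` (Wilson).
#' @export
summarise_fi <- function(scores, cutpoint = 0.21, ci_level = 0.95) {
  fi <- scores$fi[scores$valid]
  if (!length(fi)) stop("no subject has a valid frailty index")
  n_frail <- sum(fi >= cutpoint)
  ci <- proportion_ci(n_frail, length(fi), level = ci_level,
                      method = "wilson")
  list(n_valid = length(fi),
       mean = mean(fi),
       sd = if (length(fi) > 1L) stats::sd(fi) else 0,
       median = stats::median(fi),
       maximum = max(fi),
       p99 = unname(stats::quantile(fi, 0.99, type = 7)),
       n_frail = n_frail,
       prevalence_frail = n_frail / length(fi),
       prevalence_ci = ci)
}
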