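#' Code a single lab value against a reference range
#'
#' A value outside the normal range is a deficit (1); a value inside is
#' normal (0); a missing value stays missing (`NA`). Interval endpoints are
#' normal; one-sided cut-offs follow their printed inequality strictly, so
#' under "< 5.18" the value 5.18 is a deficit while under ">= 1.04" the
#' value 1.04 is normal.
#'
#' @param value Numeric lab value, or `NA`.
#' @param range A one-row reference range as returned by [panel_range()].
#' @return Integer 0, 1 or `NA`.
#' @examples
#' panel <- load_reference_panel()
#' code_value(10.0, panel_range(panel, "wbc", "male"))  # 1
#' code_value(140, panel_range(panel, "hgb", "male"))   # 0
#' @export
code_value <- function(value, range) {
  stopifnot(nrow(range) == 1L)
  if (length(value) != 1L) stop("code_value codes one value at a time")
  if (is.na(value)) return(NA_integer_)
  if (!is.numeric(value)) stop("lab value must be numeric, got ", class(value))
  normal <- switch(range$bound_style,
    interval   = value >= range$lower & value <= range$upper,
    upper_only = value < range$upper,
    lower_only = value >= range$lower,
    stop("unknown bound_style: ", range$bound_style))
  if (normal) 0L else 1L
}

#' Code one subject's lab values into a deficit vector
#'
#' Every panel variable is coded 0 (normal), 1 (deficit) or `NA` (value not
#' measured) against the reference range matching the subject's sex. Lab
#' keys not in the panel are ignored with a warning; panel variables absent
#' from `labs` are coded `NA`.
#'
#' @param labs Named numeric vector or single-row data frame of lab values,
#'   keyed by panel variable names.
#' @param sex `"male"` or `"female"`.
#' @param panel An `fi_panel`; default is the bundled 22-variable panel.
#' @return Named integer vector over the full panel, in panel order.
#' @export
code_subject <- function(labs, sex, panel = load_reference_panel()) {
  if (is.data.frame(labs)) {
    stopifnot(nrow(labs) == 1L)
    labs <- unlist(labs[1L, , drop = TRUE])
  }
  if (is.null(names(labs)) && length(labs))
    stop("labs must be named by panel variable")
  if (is.na(sex) || !sex %in% c("male", "female"))
    stop("sex must be 'male' or 'female' to resolve sex-specific ranges")
  vars <- panel_variables(panel)
  extra <- setdiff(names(labs), vars)
  if (length(extra))
    warning("ignoring lab keys not in panel: ", paste(extra, collapse = ", "))
  codes <- vapply(vars, function(v) {
    val <- if (v %in% names(labs)) as.numeric(labs[[v]]) else NA_real_
    code_value(val, panel_range(panel, v, sex))
  }, integer(1))
  codes
}

#' Code every subject of a cohort into a deficit matrix
#'
#' @param cohort A cohort data frame with a `sex` column and one column per
#'   panel variable (see [read_cohort()] for the header contract).
#' @param panel An `fi_panel`.
#' @return Integer matrix, subjects x panel variables, entries 0/1/`NA`,
#'   with subject ids as row names when an `id` column is present.
#' @export
code_cohort <- function(cohort, panel = load_reference_panel()) {
  vars <- panel_variables(panel)
  present <- intersect(vars, names(cohort))
  codes <- matrix(NA_integer_, nrow(cohort), length(vars),
                  dimnames = list(cohort$id, vars))
  # vectorised per (variable, sex) block: one range lookup per block
  for (v in present) {
    val <- as.numeric(cohort[[v]])
    for (sx in c("male", "female")) {
      rows <- which(cohort$sex == sx)
      if (!length(rows)) next
      rg <- panel_range(panel, v, sx)
      x <- val[rows]
      normal <- switch(rg$bound_style,
        interval   = x >= rg$lower & x <= rg$upper,
        upper_only = x < rg$upper,
        lower_only = x >= rg$lower)
      codes[rows, v] <- ifelse(is.na(x), NA_integer_, as.integer(!normal))
    }
  }
  codes
}
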