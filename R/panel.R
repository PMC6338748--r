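#' Load a laboratory reference-range panel
#'
#' Reads a reference-range configuration table describing, for each lab
#' variable and sex scope, the interval of values considered normal. Values
#' outside the range are health deficits. The bundled default panel
#' (`"table3"`) carries the 22-variable nonagenarian panel with sex-specific
#' ranges for the blood-count variables and one-sided cut-offs for the
#' lipids, direct bilirubin and ALT, exactly as printed in its source; the
#' `"table3_mcv82"` variant replaces the female MCV lower bound of 32.6 fL
#' (a suspected misprint) with the conventional 82.6 fL. Pipeline behaviour
#' must not depend on which of the two is loaded.
#'
#' Bound styles:
#' \describe{
#'   \item{`interval`}{normal iff `lower <= value <= upper` (endpoints
#'     normal).}
#'   \item{`upper_only`}{printed as "< upper": normal iff `value < upper`
#'     (the bound itself is a deficit).}
#'   \item{`lower_only`}{printed as ">= lower": normal iff
#'     `value >= lower` (the bound itself is normal).}
#' }
#'
#' @param source `"table3"`, `"table3_mcv82"`, the path of a panel CSV with
#'   columns `variable, label, sex, lower, upper, bound_style, units`, or a
#'   data frame with those columns.
#' @return A data frame of class `fi_panel`, one row per (variable, sex)
#'   entry, with attribute `variables` giving the panel's variable names in
#'   panel order.
#' @examples
#' panel <- load_reference_panel()
#' length(panel_variables(panel))  # 22
#' @export
load_reference_panel <- function(source = "table3") {
  if (is.data.frame(source)) {
    raw <- source
  } else if (source %in% c("table3", "table3_mcv82")) {
    path <- system.file("extdata", paste0("panel_", source, ".csv"),
                        package = "filab", mustWork = TRUE)
    raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  } else {
    if (!file.exists(source))
      stop("panel config not found: ", source)
    raw <- utils::read.csv(source, stringsAsFactors = FALSE)
  }
  needed <- c("variable", "sex", "lower", "upper", "bound_style")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols))
    stop("panel config lacks columns: ", paste(missing_cols, collapse = ", "))
  if (!nrow(raw)) stop("panel config is empty")
  if (!"units" %in% names(raw)) raw$units <- NA_character_
  if (!"label" %in% names(raw)) raw$label <- raw$variable
  raw$lower <- as.numeric(raw$lower)
  raw$upper <- as.numeric(raw$upper)

  bad_sex <- setdiff(unique(raw$sex), c("male", "female", "any"))
  if (length(bad_sex))
    stop("unknown sex scope in panel: ", paste(bad_sex, collapse = ", "))
  bad_style <- setdiff(unique(raw$bound_style),
                       c("interval", "upper_only", "lower_only"))
  if (length(bad_style))
    stop("unknown bound_style in panel: ", paste(bad_style, collapse = ", "))

  key <- paste(raw$variable, raw$sex)
  if (anyDuplicated(key))
    stop("duplicate (variable, sex) entry in panel: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  # a variable is either sex-split (male + female rows) or a single any row
  for (v in unique(raw$variable)) {
    sx <- raw$sex[raw$variable == v]
    ok <- identical(sort(sx), c("female", "male")) || identical(sx, "any")
    if (!ok)
      stop("variable '", v, "' must have either one 'any' entry or both ",
           "'male' and 'female' entries")
  }

  no_bound <- is.na(raw$lower) & is.na(raw$upper)
  if (any(no_bound))
    stop("panel entries without any bound: ",
         paste(key[no_bound], collapse = ", "))
  both <- !is.na(raw$lower) & !is.na(raw$upper)
  if (any(both & raw$lower >= raw$upper))
    stop("lower bound must be below upper bound for: ",
         paste(key[both & raw$lower >= raw$upper], collapse = ", "))
  if (any(raw$bound_style == "interval" & !both))
    stop("interval entries need both bounds")
  if (any(raw$bound_style == "upper_only" & is.na(raw$upper)))
    stop("upper_only entries need an upper bound")
  if (any(raw$bound_style == "lower_only" & is.na(raw$lower)))
    stop("lower_only entries need a lower bound")

  structure(raw[, c("variable", "label", "sex", "lower", "upper",
                    "bound_style", "units")],
            variables = unique(raw$variable),
            class = c("fi_panel", "data.frame"))
}

#' Panel variable names, in panel order
#'
#' @param panel An `fi_panel` from [load_reference_panel()].
#' @return Character vector of variable names.
#' @export
panel_variables <- function(panel) {
  v <- attr(panel, "variables")
  if (is.null(v)) unique(panel$variable) else v
}

#' Resolve the reference range for one variable and sex
#'
#' @param panel An `fi_panel`.
#' @param variable Panel variable name.
#' @param sex `"male"` or `"female"`.
#' @return One-row data frame (a single reference range).
#' @export
panel_range <- function(panel, variable, sex) {
  if (!sex %in% c("male", "female"))
    stop("sex must be 'male' or 'female', got: ", sex)
  hit <- panel[panel$variable == variable &
                 (panel$sex == sex | panel$sex == "any"), , drop = FALSE]
  if (nrow(hit) == 0L)
    stop("no reference range for variable '", variable, "'")
  if (nrow(hit) > 1L)
    stop("ambiguous reference range for '", variable, "', sex ", sex)
  hit
}

#' @export
print.fi_panel <- function(x, ...) {
  cat("Laboratory reference panel:", length(panel_variables(x)),
      "variables,", nrow(x), "entries\n")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}
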