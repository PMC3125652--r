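#' basalmorph: basal cell layer morphometry
#'
#' Measurement, shape description and group-comparison statistics for
#' basal-cell morphometry of oral epithelium. See
#' `vignette("basal-cell-morphometry", package = "basalmorph")` for the
#' methods account.
#'
#' @keywords internal
"_PACKAGE"

#' Diagnostic group labels
#'
#' The controlled vocabulary for the three diagnostic groups, in the order
#' used throughout the package: normal buccal mucosa, oral leukoplakia,
#' well-differentiated squamous cell carcinoma.
#' @export
GROUP_LEVELS <- c("normal", "leukoplakia", "scc")

#' Circle constant used by the shape descriptors
#'
#' The form perimeter is `4 * c * area / perimeter^2`. The mathematically
#' correct circle constant is `pi`; the classical morphometry literature
#' sometimes uses the rational approximation `22/7`. Because the choice is a
#' global positive scaling of the descriptor, every downstream ANOVA, t and
#' rank statistic is invariant to it. The package default can be set with
#' `options(basalmorph.circle = "22/7")`.
#'
#' @param circle `"pi"` or `"22/7"`.
#' @return The numeric constant.
#' @export
circle_constant <- function(circle = getOption("basalmorph.circle", "pi")) {
  circle <- match.arg(circle, c("pi", "22/7"))
  if (circle == "pi") pi else 22 / 7
}

#' Form perimeter (circularity) of a closed outline
#'
#' `4 * c * area / perimeter^2`, where `c` is the circle constant. A circle
#' scores exactly 1 (with `c = pi`); indented or elongated outlines score
#' lower. Measured data can exceed 1 because area and perimeter are
#' estimated independently; such values are legitimate and are never
#' clipped.
#'
#' @param area Area (square microns or any consistent unit), positive.
#' @param perimeter Perimeter (same length unit), positive.
#' @param circle Circle constant choice, see [circle_constant()].
#' @return Dimensionless circularity score, vectorized over inputs.
#' @examples
#' r <- 3
#' form_pe(pi * r^2, 2 * pi * r) # exactly 1
#' @export
form_pe <- function(area, perimeter,
                    circle = getOption("basalmorph.circle", "pi")) {
  stopifnot_positive(area, "area")
  stopifnot_positive(perimeter, "perimeter")
  4 * circle_constant(circle) * area / perimeter^2
}

#' Contour index (boundary irregularity) of a closed outline
#'
#' `perimeter / sqrt(area)`. A circle scores `2 * sqrt(pi)`, about 3.545;
#' values rise with indentations or convolutions of the outline. At fixed
#' area the index is strictly increasing in perimeter, and it relates to the
#' form perimeter through `ci^2 * form_pe = 4 * c`.
#'
#' @inheritParams form_pe
#' @return Dimensionless irregularity score, vectorized over inputs.
#' @export
contour_index <- function(area, perimeter) {
  stopifnot_positive(area, "area")
  stopifnot_positive(perimeter, "perimeter")
  perimeter / sqrt(area)
}

#' Nuclear-cytoplasmic ratio
#'
#' Nuclear area divided by cytoplasmic area, `NA / (CA - NA)`. Equal nuclear
#' and cytoplasmic compartments give 1; the ratio rises in dysplasia as the
#' nucleus enlarges at the expense of cytoplasm.
#'
#' @param nuclear_area Nuclear profile area, positive.
#' @param cell_area Whole-cell profile area, strictly larger than
#'   `nuclear_area`.
#' @return Dimensionless ratio, vectorized over inputs.
#' @export
nc_ratio <- function(nuclear_area, cell_area) {
  stopifnot_positive(nuclear_area, "nuclear_area")
  stopifnot_positive(cell_area, "cell_area")
  if (any(nuclear_area >= cell_area)) {
    bad <- which(nuclear_area >= cell_area)
    bm_domain_error(sprintf(
      "nuclear_area must be strictly smaller than cell_area (implausible record%s at index %s)",
      if (length(bad) > 1L) "s" else "",
      paste(utils::head(bad, 5L), collapse = ", ")))
  }
  nuclear_area / (cell_area - nuclear_area)
}

measurement_cols <- c("cell_area", "cell_perimeter",
                      "nuclear_area", "nuclear_perimeter")

#' Derive shape and nuclear-cytoplasmic descriptors for measurement records
#'
#' Applies [form_pe()] and [contour_index()] to the cellular and nuclear
#' compartments and [nc_ratio()] to the area pair, adding five columns to a
#' validated measurement table: `cellular_form_pe`, `nuclear_form_pe`,
#' `cellular_ci`, `nuclear_ci`, `nc_ratio`.
#'
#' Form perimeter values above 1 (geometrically impossible for a true simple
#' closed curve, but present in measured data) are kept as-is; a single
#' warning reports how many rows are affected.
#'
#' @param records Measurement data frame with columns `case_id`, `group`,
#'   `cell_area`, `cell_perimeter`, `nuclear_area`, `nuclear_perimeter`
#'   (see [read_measurements()]).
#' @param circle Circle constant choice, see [circle_constant()].
#' @return The input data frame with the five descriptor columns appended.
#' @examples
#' derive_descriptors(table2_fixture())
#' @export
derive_descriptors <- function(records,
                               circle = getOption("basalmorph.circle", "pi")) {
  records <- validate_measurements(records)
  out <- records
  ids <- as.character(records$case_id)
  with_case <- function(expr) {
    tryCatch(expr, bm_domain_error = function(e) {
      bm_domain_error(sprintf("%s [while deriving descriptors for case(s) %s]",
                              conditionMessage(e),
                              paste(utils::head(ids, 3L), collapse = ", ")))
    })
  }
  out$cellular_form_pe <- with_case(
    form_pe(records$cell_area, records$cell_perimeter, circle))
  out$nuclear_form_pe <- with_case(
    form_pe(records$nuclear_area, records$nuclear_perimeter, circle))
  out$cellular_ci <- with_case(
    contour_index(records$cell_area, records$cell_perimeter))
  out$nuclear_ci <- with_case(
    contour_index(records$nuclear_area, records$nuclear_perimeter))
  out$nc_ratio <- with_case(
    nc_ratio(records$nuclear_area, records$cell_area))
  over <- out$cellular_form_pe > 1 | out$nuclear_form_pe > 1
  if (any(over)) {
    warning(sprintf(
      "form perimeter exceeds 1 for %d record(s) (%s): kept unclipped",
      sum(over), paste(utils::head(ids[over], 5L), collapse = ", ")),
      call. = FALSE)
  }
  out
}

descriptor_cols <- c("cellular_form_pe", "nuclear_form_pe",
                     "cellular_ci", "nuclear_ci", "nc_ratio")

#' Per-group descriptive statistics
#'
#' For one measured or derived variable, computes per diagnostic group the
#' sample size, mean, standard deviation (n - 1 denominator), standard error
#' of the mean, and the t-based 95% confidence interval for the mean.
#'
#' @param data Data frame with a `group` column and the requested variable
#'   (descriptor columns are derived on the fly when absent).
#' @param variable Name of the column to summarize.
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return A data frame with one row per group: `group`, `variable`, `n`,
#'   `mean`, `sd`, `sem`, `ci95_low`, `ci95_high`.
#' @examples
#' summarize_groups(table2_fixture(), "nuclear_area")
#' @export
summarize_groups <- function(data, variable, conf_level = 0.95) {
  if (!variable %in% names(data)) {
    if (variable %in% descriptor_cols && all(measurement_cols %in% names(data))) {
      data <- suppressWarnings(derive_descriptors(data))
    } else {
      bm_config_error(sprintf(
        "unknown variable '%s'; available: %s", variable,
        paste(setdiff(names(data), c("case_id", "group")), collapse = ", ")))
    }
  }
  if (!"group" %in% names(data)) bm_config_error("data has no 'group' column")
  g <- factor(as.character(data$group), levels = GROUP_LEVELS)
  g <- droplevels(g)
  out <- do.call(rbind, lapply(split(data[[variable]], g), function(x) {
    n <- length(x)
    if (n < 2L) bm_data_error(sprintf(
      "need at least 2 records per group to summarize '%s' (got %d)",
      variable, n))
    m <- mean(x)
    s <- stats::sd(x)
    sem <- s / sqrt(n)
    half <- stats::qt(1 - (1 - conf_level) / 2, df = n - 1) * sem
    data.frame(n = n, mean = m, sd = s, sem = sem,
               ci95_low = m - half, ci95_high = m + half)
  }))
  data.frame(group = factor(levels(g), levels = GROUP_LEVELS),
             variable = variable, out, row.names = NULL)
}
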