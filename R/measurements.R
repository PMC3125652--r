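# Measurement-table I/O. The on-disk dialect is a plain UTF-8 CSV with
# header case_id,group,cell_area,cell_perimeter,nuclear_area,nuclear_perimeter;
# areas in square microns, perimeters in microns, decimal point.

#' Validate a measurement table
#'
#' Checks the contract every measurement record must satisfy: the four size
#' measurements are strictly positive and finite, the nuclear area is
#' strictly smaller than the cell area (the nucleus lies inside the cell),
#' and the group label is one of `normal`, `leukoplakia`, `scc`.
#' Violating rows are reported individually by `case_id`; nothing is
#' silently dropped.
#'
#' @param records Data frame to validate.
#' @return The validated data frame with `group` as a factor with the
#'   standard level order.
#' @export
validate_measurements <- function(records) {
  if (!is.data.frame(records)) bm_data_error("measurements must be a data frame")
  need <- c("case_id", "group", measurement_cols)
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols)) {
    bm_data_error(sprintf("missing column(s): %s",
                          paste(missing_cols, collapse = ", ")))
  }
  if (nrow(records) == 0L) bm_data_error("measurement table has no rows")
  bad_group <- !as.character(records$group) %in% GROUP_LEVELS
  problems <- character()
  for (cn in measurement_cols) {
    v <- records[[cn]]
    bad <- !is.numeric(v) | !is.finite(v) | v <= 0
    if (any(bad)) {
      problems <- c(problems, sprintf(
        "%s: non-positive or non-numeric %s", records$case_id[bad], cn))
    }
  }
  ok_num <- Reduce(`&`, lapply(records[measurement_cols], function(v) {
    is.numeric(v) & is.finite(v) & v > 0
  }))
  bad_na <- ok_num & records$nuclear_area >= records$cell_area
  if (any(bad_na)) {
    problems <- c(problems, sprintf(
      "%s: nuclear_area (%.3f) >= cell_area (%.3f)",
      records$case_id[bad_na], records$nuclear_area[bad_na],
      records$cell_area[bad_na]))
  }
  if (any(bad_group)) {
    problems <- c(problems, sprintf(
      "%s: unknown group '%s'", records$case_id[bad_group],
      as.character(records$group)[bad_group]))
  }
  if (length(problems)) {
    bm_data_error(paste0(
      sprintf("%d invalid measurement record(s):\n", length(problems)),
      paste("  -", utils::head(problems, 10L), collapse = "\n")))
  }
  records$group <- factor(as.character(records$group), levels = GROUP_LEVELS)
  records
}

#' Read a measurement table from CSV
#'
#' @param path Path to a CSV file in the standard dialect (header
#'   `case_id,group,cell_area,cell_perimeter,nuclear_area,nuclear_perimeter`).
#' @return A validated measurement data frame.
#' @seealso [write_measurements()], [table2_fixture()]
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) bm_io_error(sprintf("no such file: %s", path))
  d <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8"),
    error = function(e) bm_io_error(sprintf("cannot parse %s: %s", path,
                                            conditionMessage(e))))
  validate_measurements(d)
}

#' Write a measurement table to CSV
#'
#' Inverse of [read_measurements()]; re-serializing an unmodified table
#' reproduces the file byte for byte (numbers are written with their full
#' precision, group as plain character).
#'
#' @param records Measurement data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(records, path) {
  records <- validate_measurements(records)
  out <- records[, c("case_id", "group", measurement_cols)]
  out$group <- as.character(out$group)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' The packaged reference dataset (70 cases)
#'
#' Per-case mean cell area, cell perimeter, nuclear area and nuclear
#' perimeter of basal cells, for 10 normal buccal mucosa, 30 oral
#' leukoplakia and 30 well-differentiated squamous cell carcinoma cases
#' (areas in square microns, perimeters in microns; each case value is the
#' published mean over 5-10 microscopic fields of 5-7 selected basal
#' cells). Rows are stored in the published order: leukoplakia, SCC, normal.
#'
#' @return A validated measurement data frame with 70 rows.
#' @export
table2_fixture <- function() {
  read_measurements(system.file("extdata", "table2_morphometry.csv",
                                package = "basalmorph", mustWork = TRUE))
}

#' Path to the packaged reference CSV
#' @return File path of the CSV shipped with the package.
#' @export
table2_fixture_path <- function() {
  system.file("extdata", "table2_morphometry.csv",
              package = "basalmorph", mustWork = TRUE)
}
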