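# Calibrated per-object measurement of co-registered cell / nucleus label
# masks, plus the on-disk dataset layout (16-bit TIFF masks + sidecar JSON).

#' Construct a calibrated cell/nucleus label-mask pair
#'
#' Bundles a cell label mask, the co-registered nucleus label mask and the
#' micron-per-pixel calibration, validating the co-registration contract:
#' identical raster dimensions, every nucleus label present among the cell
#' labels, and every nucleus pixel lying inside its cell's pixel set.
#'
#' @param cell_mask Integer matrix; 0 = background, k > 0 = cell k.
#' @param nucleus_mask Integer matrix of identical shape; label k marks the
#'   nucleus of cell k.
#' @param microns_per_pixel Isotropic calibration factor, strictly positive.
#' @return An object of class `label_mask_pair`.
#' @export
label_mask_pair <- function(cell_mask, nucleus_mask, microns_per_pixel) {
  if (!is.matrix(cell_mask) || !is.matrix(nucleus_mask)) {
    bm_domain_error("masks must be matrices")
  }
  if (!all(dim(cell_mask) == dim(nucleus_mask))) {
    bm_domain_error(sprintf(
      "mask dimensions differ: cell %dx%d vs nucleus %dx%d",
      nrow(cell_mask), ncol(cell_mask), nrow(nucleus_mask), ncol(nucleus_mask)))
  }
  stopifnot_positive(microns_per_pixel, "microns_per_pixel")
  nuc_labels <- sort(unique(nucleus_mask[nucleus_mask > 0]))
  cell_labels <- sort(unique(cell_mask[cell_mask > 0]))
  orphan <- setdiff(nuc_labels, cell_labels)
  if (length(orphan)) {
    bm_domain_error(sprintf("nucleus label(s) without a matching cell: %s",
                            paste(orphan, collapse = ", ")))
  }
  outside <- nucleus_mask > 0 & cell_mask != nucleus_mask
  if (any(outside)) {
    bad <- sort(unique(nucleus_mask[outside]))
    bm_domain_error(sprintf(
      "nucleus pixels outside their cell for label(s): %s",
      paste(bad, collapse = ", ")))
  }
  structure(list(cell_mask = cell_mask, nucleus_mask = nucleus_mask,
                 microns_per_pixel = microns_per_pixel),
            class = "label_mask_pair")
}

#' Measure all complete objects in one field
#'
#' Emulates interactive outline tracing on one microscopic field: every
#' labeled cell that does not touch the raster border and has a traceable
#' nucleus is measured, yielding cell area (CA), cell perimeter (CP),
#' nuclear area (NA) and nuclear perimeter (NP) in calibrated physical
#' units. Cells clipped by the image border (the stand-in for overlapping
#' or incomplete cells) and cells without a nucleus label are excluded,
#' with the reason recorded.
#'
#' @param pair A [label_mask_pair()].
#' @param smooth_sigma Contour smoothing, see [extract_contours()].
#' @return Data frame with one row per measured object: `label`,
#'   `cell_area`, `cell_perimeter`, `nuclear_area`, `nuclear_perimeter`.
#'   Exclusions are recorded in attribute `"excluded"` (columns `label`,
#'   `reason`).
#' @export
measure_field <- function(pair, smooth_sigma = 1.5) {
  if (!inherits(pair, "label_mask_pair")) {
    pair <- do.call(label_mask_pair, as.list(pair))
  }
  cal <- pair$microns_per_pixel
  cm <- pair$cell_mask
  nm <- pair$nucleus_mask
  labels <- sort(unique(cm[cm > 0]))
  nr <- nrow(cm); nc <- ncol(cm)
  rows <- list()
  excluded <- data.frame(label = integer(), reason = character())
  drop <- function(k, why) {
    excluded[nrow(excluded) + 1L, ] <<- list(as.integer(k), why)
  }
  border <- matrix(FALSE, nr, nc)
  border[c(1L, nr), ] <- TRUE
  border[, c(1L, nc)] <- TRUE
  for (k in labels) {
    sel <- cm == k
    if (any(sel & border)) { drop(k, "touches image border"); next }
    if (!any(nm == k)) { drop(k, "no nucleus label"); next }
    cpoly <- tryCatch(trace_label(cm * sel, k, smooth_sigma),
                      bm_object_skip = function(e) e)
    if (inherits(cpoly, "condition")) {
      drop(k, paste("cell outline:", conditionMessage(cpoly))); next
    }
    npoly <- tryCatch(trace_label(nm * (nm == k), k, smooth_sigma),
                      bm_object_skip = function(e) e)
    if (inherits(npoly, "condition")) {
      drop(k, paste("nucleus outline:", conditionMessage(npoly))); next
    }
    ca <- polygon_area(cpoly, cal)
    na_ <- polygon_area(npoly, cal)
    if (na_ >= ca) { drop(k, "nuclear area not smaller than cell area"); next }
    rows[[length(rows) + 1L]] <- data.frame(
      label = as.integer(k),
      cell_area = ca,
      cell_perimeter = polygon_perimeter(cpoly, cal),
      nuclear_area = na_,
      nuclear_perimeter = polygon_perimeter(npoly, cal))
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(label = integer(), cell_area = numeric(),
               cell_perimeter = numeric(), nuclear_area = numeric(),
               nuclear_perimeter = numeric())
  attr(out, "excluded") <- excluded
  out
}

#' Aggregate per-object field measurements into one case record
#'
#' Within each field the `max_cells_per_field` largest objects by cell area
#' are kept (the classical selection rule: the 5-7 largest cells with a
#' clear outline per field), then the four measurements are aggregated
#' across all kept objects into a single per-case record, matching the
#' one-row-per-case layout of the reference dataset. The aggregation
#' statistic defaults to the mean; the source protocol does not state it,
#' so it is configurable.
#'
#' @param fields List of per-field measurement data frames from
#'   [measure_field()].
#' @param case_id Case identifier for the output record.
#' @param group Diagnostic group label.
#' @param max_cells_per_field Per-field cap on kept objects (default 7).
#' @param stat Aggregation statistic, `"mean"` (default) or `"median"`.
#' @return A one-row measurement data frame.
#' @export
aggregate_case <- function(fields, case_id, group, max_cells_per_field = 7L,
                           stat = c("mean", "median")) {
  stat <- match.arg(stat)
  agg <- if (stat == "mean") mean else stats::median
  if (!is.list(fields) || is.data.frame(fields)) fields <- list(fields)
  stopifnot_positive(max_cells_per_field, "max_cells_per_field")
  kept <- lapply(fields, function(f) {
    if (nrow(f) == 0L) return(f)
    f[order(f$cell_area, decreasing = TRUE)[
      seq_len(min(nrow(f), max_cells_per_field))], , drop = FALSE]
  })
  all_rows <- do.call(rbind, kept)
  if (is.null(all_rows) || nrow(all_rows) == 0L) {
    bm_data_error(sprintf("case %s: no measurable objects survive", case_id))
  }
  rec <- data.frame(
    case_id = case_id, group = group,
    cell_area = agg(all_rows$cell_area),
    cell_perimeter = agg(all_rows$cell_perimeter),
    nuclear_area = agg(all_rows$nuclear_area),
    nuclear_perimeter = agg(all_rows$nuclear_perimeter),
    stringsAsFactors = FALSE)
  validate_measurements(rec)
}

# ---- on-disk layout: 16-bit TIFF masks + sidecar JSON per field ----

mask_to_raster <- function(mask) {
  if (max(mask) > 65535L) bm_domain_error("more than 65535 labels")
  mask / 65535
}

raster_to_mask <- function(x) {
  if (is.array(x) && length(dim(x)) == 3L) x <- x[, , 1]
  matrix(as.integer(round(x * 65535)), nrow(x), ncol(x))
}

#' Write one field's mask pair and sidecar to a dataset directory
#'
#' Masks are stored as single-channel 16-bit TIFF (label k encoded as
#' k/65535); a sidecar JSON per field carries the calibration, case id,
#' group and field index.
#'
#' @param pair A [label_mask_pair()].
#' @param dir Dataset directory (created if needed).
#' @param case_id,group,field Identity of the field.
#' @return The sidecar path, invisibly.
#' @export
write_mask_pair <- function(pair, dir, case_id, group, field) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stem <- sprintf("%s_f%02d", case_id, field)
  cell_file <- paste0(stem, "_cell.tif")
  nuc_file <- paste0(stem, "_nucleus.tif")
  tiff::writeTIFF(mask_to_raster(pair$cell_mask), file.path(dir, cell_file),
                  bits.per.sample = 16L)
  tiff::writeTIFF(mask_to_raster(pair$nucleus_mask), file.path(dir, nuc_file),
                  bits.per.sample = 16L)
  sidecar <- file.path(dir, paste0(stem, ".json"))
  jsonlite::write_json(list(
    case_id = case_id, group = group, field = field,
    microns_per_pixel = pair$microns_per_pixel,
    cell_mask = cell_file, nucleus_mask = nuc_file),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

read_mask_image <- function(path) {
  if (!file.exists(path)) bm_io_error(sprintf("no such mask file: %s", path))
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    bm_io_error(sprintf("unsupported mask format '%s' (%s)", ext, path)))
  raster_to_mask(img)
}

#' Read one field's mask pair from its sidecar JSON
#'
#' @param sidecar Path to a field sidecar written by [write_mask_pair()].
#' @return A list with `pair` ([label_mask_pair()]), `case_id`, `group`,
#'   `field`.
#' @export
read_mask_pair <- function(sidecar) {
  if (!file.exists(sidecar)) bm_io_error(sprintf("no such sidecar: %s", sidecar))
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  need <- c("case_id", "group", "field", "microns_per_pixel",
            "cell_mask", "nucleus_mask")
  if (!all(need %in% names(meta))) {
    bm_io_error(sprintf("sidecar %s lacks field(s): %s", sidecar,
                        paste(setdiff(need, names(meta)), collapse = ", ")))
  }
  dir <- dirname(sidecar)
  pair <- label_mask_pair(read_mask_image(file.path(dir, meta$cell_mask)),
                          read_mask_image(file.path(dir, meta$nucleus_mask)),
                          meta$microns_per_pixel)
  list(pair = pair, case_id = meta$case_id, group = meta$group,
       field = meta$field)
}
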