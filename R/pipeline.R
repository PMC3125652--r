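# High-level pipeline commands tying the stages together. These back the
# thin command-line front-end in inst/cli/basalmorph.R; the functions are
# the primary interface.

log_msg <- function(...) message(sprintf(...))

run_manifest <- function(extra = list()) {
  c(list(package = "basalmorph",
         package_version = as.character(utils::packageVersion("basalmorph")),
         r_version = paste(R.version$major, R.version$minor, sep = "."),
         timestamp = NULL),   # timestamps deliberately omitted: runs are bit-reproducible
    extra)
}

#' Simulate a synthetic label-mask dataset on disk
#'
#' Generates the full synthetic design and writes masks, sidecars, the
#' ground-truth object table and a `manifest.json` recording the complete
#' spec including the seed. Deterministic per seed.
#'
#' @param out_dir Output dataset directory.
#' @param spec A [synthetic_spec()]; default [default_synthetic_spec()].
#' @param seed Overrides the spec seed when given.
#' @return The ground-truth data frame, invisibly.
#' @export
cmd_simulate <- function(out_dir, spec = default_synthetic_spec(),
                         seed = spec$seed) {
  truth <- generate_dataset(spec, dir = out_dir, seed = seed)
  log_msg("simulate: wrote %d objects over %d fields to %s (seed %d)",
          nrow(truth), length(unique(paste(truth$case_id, truth$field))),
          out_dir, seed)
  invisible(truth)
}

#' Measure a mask dataset into a per-case measurement CSV
#'
#' Runs the calibrated measurement over every field sidecar found in
#' `data_dir`, aggregates per case (largest-cells selection rule, then
#' mean) and writes the standard measurement CSV. Per-reason exclusion
#' counts are logged to stderr.
#'
#' @param data_dir Dataset directory containing `*.json` field sidecars.
#' @param out_csv Output CSV path.
#' @param max_cells_per_field Per-field cap on kept cells (default 7).
#' @param smooth_sigma Contour smoothing, see [extract_contours()].
#' @return The measurement data frame, invisibly.
#' @export
cmd_measure <- function(data_dir, out_csv, max_cells_per_field = 7L,
                        smooth_sigma = 1.5) {
  if (!dir.exists(data_dir)) bm_io_error(sprintf("no such directory: %s", data_dir))
  sidecars <- sort(list.files(data_dir, pattern = "\\.json$", full.names = TRUE))
  sidecars <- sidecars[basename(sidecars) != "manifest.json"]
  if (!length(sidecars)) {
    bm_io_error(sprintf("no field sidecars (*.json) found in %s", data_dir))
  }
  by_case <- list()
  meta_of <- list()
  exclusions <- character()
  for (s in sidecars) {
    fl <- read_mask_pair(s)
    m <- measure_field(fl$pair, smooth_sigma = smooth_sigma)
    exclusions <- c(exclusions, attr(m, "excluded")$reason)
    by_case[[fl$case_id]] <- c(by_case[[fl$case_id]], list(m))
    meta_of[[fl$case_id]] <- fl$group
  }
  if (length(exclusions)) {
    tab <- table(exclusions)
    for (nm in names(tab)) log_msg("measure: excluded %d object(s): %s",
                                   tab[[nm]], nm)
  }
  recs <- do.call(rbind, lapply(names(by_case), function(cid) {
    aggregate_case(by_case[[cid]], cid, meta_of[[cid]],
                   max_cells_per_field = max_cells_per_field)
  }))
  write_measurements(recs, out_csv)
  log_msg("measure: wrote %d case records to %s", nrow(recs), out_csv)
  invisible(recs)
}

#' Analyze a measurement table and write the report bundle
#'
#' Derives the shape and N:C descriptors, runs the full group comparison
#' and serializes the report (CSV tables + JSON + run manifest).
#'
#' @param input Path to a measurement CSV, or `"table2"` for the packaged
#'   reference dataset.
#' @param out_dir Report output directory.
#' @param circle Circle constant choice, see [circle_constant()].
#' @param alpha Significance threshold.
#' @return The `morph_report`, invisibly.
#' @export
cmd_analyze <- function(input, out_dir,
                        circle = getOption("basalmorph.circle", "pi"),
                        alpha = 0.05) {
  path <- if (identical(input, "table2")) table2_fixture_path() else input
  records <- read_measurements(path)
  report <- run_full_comparison(records, alpha = alpha, circle = circle)
  write_report(report, out_dir)
  jsonlite::write_json(
    run_manifest(list(command = "analyze", input = basename(path),
                      input_md5 = unname(tools::md5sum(path)),
                      n_cases = nrow(records), circle = circle,
                      alpha = alpha)),
    file.path(out_dir, "run_manifest.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  log_msg("analyze: %d cases -> %s", nrow(records), out_dir)
  invisible(report)
}
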