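# Seeded synthetic-histology generator. Produces label-mask fields (and
# fast tabular datasets that bypass imaging) whose three diagnostic groups
# reproduce the group-level size and boundary-irregularity structure of the
# packaged reference dataset, so the whole pipeline is testable without any
# external data.
#
# Geometry: star-convex radial perturbation. A cell outline is
# r(phi) = R * (1 + u(phi)) with u a smooth periodic perturbation built
# from harmonics k = 2..6 with random phases; its RMS amplitude is the
# per-group "irregularity" knob. The polygon is rescaled analytically so
# its shoelace area hits the target exactly. To second order the expected
# form perimeter of this family is 1 - 17 * irregularity^2 (equal variance
# across the five harmonics), which gives the closed-form mapping between
# the knob and the shape axis used both ways below.

PERT_HARMONICS <- 2:6

#' Expected form perimeter of the star-convex perturbation family
#'
#' Closed-form (second-order) mapping from the generator's irregularity
#' knob (RMS relative radial perturbation over harmonics 2-6) to the
#' expected form perimeter of the rendered outline, and its inverse.
#'
#' @param irregularity RMS relative radial perturbation, >= 0.
#' @return Expected form perimeter in (0, 1].
#' @export
irregularity_to_form_pe <- function(irregularity) {
  if (any(irregularity < 0)) bm_domain_error("irregularity must be >= 0")
  pmax(1 - 17 * irregularity^2, 0.05)
}

#' @rdname irregularity_to_form_pe
#' @param form_pe_target Target mean form perimeter; values >= 1 map to a
#'   circular boundary (irregularity 0).
#' @export
form_pe_to_irregularity <- function(form_pe_target) {
  stopifnot_positive(form_pe_target, "form_pe_target")
  sqrt(pmax(0, 1 - form_pe_target) / 17)
}

#' Per-group generative parameters
#'
#' @param group Diagnostic group label.
#' @param cell_area_mean,cell_area_sd Per-case cell area distribution, um^2.
#' @param nuclear_area_mean,nuclear_area_sd Per-case nuclear area
#'   distribution, um^2.
#' @param nucleus_fraction_mean,nucleus_fraction_sd Per-case nuclear area
#'   fraction NA/CA, in (0, 1).
#' @param irregularity Boundary irregularity knob (0 = circular outline;
#'   larger values raise the contour index and lower the form perimeter).
#' @param form_pe_sd Per-case spread of the form perimeter used by the
#'   tabular generator.
#' @return An object of class `group_params`.
#' @export
group_params <- function(group, cell_area_mean, cell_area_sd,
                         nuclear_area_mean, nuclear_area_sd,
                         nucleus_fraction_mean, nucleus_fraction_sd,
                         irregularity = 0, form_pe_sd = 0.15) {
  group <- match.arg(group, GROUP_LEVELS)
  stopifnot_positive(cell_area_mean, "cell_area_mean")
  stopifnot_positive(cell_area_sd, "cell_area_sd")
  stopifnot_positive(nuclear_area_mean, "nuclear_area_mean")
  stopifnot_positive(nuclear_area_sd, "nuclear_area_sd")
  stopifnot_positive(nucleus_fraction_mean, "nucleus_fraction_mean")
  stopifnot_positive(nucleus_fraction_sd, "nucleus_fraction_sd")
  stopifnot_positive(form_pe_sd, "form_pe_sd")
  if (nucleus_fraction_mean >= 1) {
    bm_domain_error("nucleus_fraction_mean must be in (0, 1)")
  }
  if (irregularity < 0) bm_domain_error("irregularity must be >= 0")
  structure(list(group = group,
                 cell_area_mean = cell_area_mean, cell_area_sd = cell_area_sd,
                 nuclear_area_mean = nuclear_area_mean,
                 nuclear_area_sd = nuclear_area_sd,
                 nucleus_fraction_mean = nucleus_fraction_mean,
                 nucleus_fraction_sd = nucleus_fraction_sd,
                 irregularity = irregularity, form_pe_sd = form_pe_sd),
            class = "group_params")
}

#' Full specification of a synthetic dataset
#'
#' @param params Named list of three [group_params()], one per diagnostic
#'   group.
#' @param cases_per_group Named integer vector of case counts.
#' @param fields_per_case Length-2 range of microscopic fields per case.
#' @param cells_per_field Length-2 range of cells per field.
#' @param raster Length-2 raster dimensions (rows, cols) in pixels.
#' @param microns_per_pixel Calibration of the rendered rasters.
#' @param cell_cv Within-case per-cell coefficient of variation of cell
#'   area (the reference data report only per-case means, so this is a
#'   free parameter, default 10%).
#' @param seed Integer seed threaded through every generator operation.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(params,
                           cases_per_group = c(normal = 10L,
                                               leukoplakia = 30L, scc = 30L),
                           fields_per_case = c(5L, 10L),
                           cells_per_field = c(5L, 7L),
                           raster = c(448L, 448L),
                           microns_per_pixel = 0.2,
                           cell_cv = 0.10,
                           seed = 1L) {
  if (!is.list(params) || !setequal(names(params), GROUP_LEVELS)) {
    bm_config_error(sprintf("params must be a named list with elements %s",
                            paste(GROUP_LEVELS, collapse = ", ")))
  }
  for (p in params) {
    if (!inherits(p, "group_params")) bm_config_error("params must be group_params objects")
  }
  if (!setequal(names(cases_per_group), GROUP_LEVELS)) {
    bm_config_error("cases_per_group must be named with the three group labels")
  }
  stopifnot_positive(cases_per_group, "cases_per_group")
  stopifnot_positive(fields_per_case, "fields_per_case")
  stopifnot_positive(cells_per_field, "cells_per_field")
  stopifnot_positive(raster, "raster")
  stopifnot_positive(microns_per_pixel, "microns_per_pixel")
  stopifnot_positive(cell_cv, "cell_cv")
  if (length(fields_per_case) != 2L || length(cells_per_field) != 2L ||
      diff(fields_per_case) < 0 || diff(cells_per_field) < 0) {
    bm_config_error("fields_per_case and cells_per_field must be non-decreasing ranges")
  }
  # the raster must comfortably hold the largest expected cell away from
  # the border: compare against the 99th-percentile cell diameter
  max_area_px <- max(vapply(params, function(p)
    p$cell_area_mean + 3 * p$cell_area_sd, numeric(1))) / microns_per_pixel^2
  max_diam_px <- 2 * sqrt(max_area_px / pi) *
    (1 + 3 * max(vapply(params, `[[`, numeric(1), "irregularity")))
  if (min(raster) < 2.5 * max_diam_px) {
    bm_config_error(sprintf(
      "raster %dx%d too small for cells of diameter ~%.0f px",
      raster[1], raster[2], max_diam_px))
  }
  structure(list(params = params[GROUP_LEVELS],
                 cases_per_group = cases_per_group[GROUP_LEVELS],
                 fields_per_case = as.integer(fields_per_case),
                 cells_per_field = as.integer(cells_per_field),
                 raster = as.integer(raster),
                 microns_per_pixel = microns_per_pixel,
                 cell_cv = cell_cv, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Default synthetic specification matching the reference dataset
#'
#' Group parameters are the empirical per-case means and standard
#' deviations of the packaged 70-case reference dataset (10 normal / 30
#' leukoplakia / 30 SCC); the irregularity knob is set per group by
#' inverting the perturbation family's form-perimeter mapping at the
#' group's mean observed form perimeter (averaged over the cellular and
#' nuclear compartments; the normal group's observed values exceed the
#' isoperimetric bound of 1 and clamp to a circular boundary). Field and
#' cell counts follow the study design: 5-10 fields per case, 5-7 cells
#' per field.
#'
#' @param seed Integer seed stored in the spec.
#' @return A [synthetic_spec()].
#' @export
default_synthetic_spec <- function(seed = 1L) {
  d <- suppressWarnings(derive_descriptors(table2_fixture()))
  params <- lapply(GROUP_LEVELS, function(g) {
    x <- d[d$group == g, ]
    pe <- mean(c(mean(x$cellular_form_pe), mean(x$nuclear_form_pe)))
    group_params(
      group = g,
      cell_area_mean = mean(x$cell_area), cell_area_sd = stats::sd(x$cell_area),
      nuclear_area_mean = mean(x$nuclear_area),
      nuclear_area_sd = stats::sd(x$nuclear_area),
      nucleus_fraction_mean = mean(x$nuclear_area / x$cell_area),
      nucleus_fraction_sd = stats::sd(x$nuclear_area / x$cell_area),
      irregularity = form_pe_to_irregularity(pe))
  })
  names(params) <- GROUP_LEVELS
  synthetic_spec(params, seed = seed)
}

# Smooth periodic radial perturbation with RMS `irregularity`.
perturbation <- function(phi, irregularity) {
  if (irregularity == 0) return(rep(0, length(phi)))
  nk <- length(PERT_HARMONICS)
  amp <- sqrt(2 / nk) * irregularity   # per-harmonic amplitude: RMS = irr
  u <- rep(0, length(phi))
  for (k in PERT_HARMONICS) {
    u <- u + amp * cos(k * phi + stats::runif(1, 0, 2 * pi))
  }
  u
}

star_polygon <- function(radius, phi, center) {
  cbind(x = center[1] + radius * cos(phi), y = center[2] + radius * sin(phi))
}

#' Render one synthetic cell and its nucleus as polygons
#'
#' Draws a star-convex cell outline about its centroid using the radial
#' perturbation family, analytically rescaled so the polygon area matches
#' the target exactly, then places a nucleus strictly inside: a scaled copy
#' of the cell boundary with an independent mild perturbation, rescaled to
#' the nuclear area fraction and radially capped below the cell boundary.
#' Irregularity 0 yields a circle discretized to `n_vertices` (>= 64).
#'
#' Randomness comes from the R session RNG; callers seed it (the dataset
#' operations seed from their spec).
#'
#' @param target_area Cell area target, in the unit implied by the caller
#'   (px^2 when rendering rasters).
#' @param irregularity RMS relative radial perturbation (>= 0).
#' @param nucleus_fraction Nuclear area fraction, in (0, 1).
#' @param center Length-2 centroid (x, y); default origin.
#' @param n_vertices Boundary discretization (default 96).
#' @return List with closed vertex matrices `cell` and `nucleus` and the
#'   realized `nucleus_area`.
#' @export
render_cell <- function(target_area, irregularity, nucleus_fraction,
                        center = c(0, 0), n_vertices = 96L) {
  stopifnot_positive(target_area, "target_area")
  if (irregularity < 0) bm_domain_error("irregularity must be >= 0")
  if (nucleus_fraction <= 0 || nucleus_fraction >= 1) {
    bm_domain_error("nucleus_fraction must be in (0, 1)")
  }
  n_vertices <- max(64L, as.integer(n_vertices))
  phi <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  rc <- pmax(1 + perturbation(phi, irregularity), 0.2)
  area1 <- polygon_area(star_polygon(rc, phi, c(0, 0)))
  rc <- rc * sqrt(target_area / area1)
  # nucleus: scaled copy of the cell radius with its own mild perturbation,
  # capped strictly inside the cell boundary
  rn <- rc * (1 + perturbation(phi, min(0.05, irregularity / 2 + 0.01)))
  rn <- rn * sqrt(nucleus_fraction * target_area /
                  polygon_area(star_polygon(rn, phi, c(0, 0))))
  cap <- 0.97 * rc
  if (any(rn > cap)) {
    rn <- pmin(rn, cap)
    # capping can only shrink; keep whatever area results (still ~fraction)
  }
  cell <- star_polygon(rc, phi, center)
  nucleus <- star_polygon(rn, phi, center)
  list(cell = rbind(cell, cell[1, , drop = FALSE]),
       nucleus = rbind(nucleus, nucleus[1, , drop = FALSE]),
       nucleus_area = polygon_area(nucleus))
}

# Draw per-case (cell_area, nuclear_area) for one group, rejecting draws
# with non-positive values or nuclear_area >= cell_area.
draw_case_sizes <- function(p, n) {
  rejected <- 0L
  ca <- numeric(n); na_ <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      a <- stats::rnorm(1, p$cell_area_mean, p$cell_area_sd)
      b <- stats::rnorm(1, p$nuclear_area_mean, p$nuclear_area_sd)
      if (a > 0 && b > 0 && b < a) break
      rejected <- rejected + 1L
    }
    ca[i] <- a; na_[i] <- b
  }
  list(cell_area = ca, nuclear_area = na_, rejected = rejected)
}

# draw uniformly from an integer range; robust to degenerate ranges
# (sample(2:2, 1) would draw from 1:2)
sample_range <- function(r) if (r[1] == r[2]) r[1] else sample(r[1]:r[2], 1L)

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= lo | x >= hi)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= lo | x[bad] >= hi]
  }
  x
}

#' Generate a tabular measurement dataset (no imaging)
#'
#' Draws per-case cell and nuclear areas from the group distributions
#' (truncated to positivity and nuclear < cell) and derives the perimeters
#' from per-case form-perimeter draws centered on the group's irregularity
#' via [irregularity_to_form_pe()]: `P = sqrt(4 * pi * A / form_pe)`.
#' Deterministic given the spec seed.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Overrides `spec$seed` when given.
#' @return A validated measurement data frame with attribute
#'   `"rejected_fraction"`, the fraction of size draws rejected by the
#'   truncation rule.
#' @export
generate_tabular <- function(spec, seed = spec$seed) {
  if (!inherits(spec, "synthetic_spec")) bm_config_error("spec must be a synthetic_spec")
  set.seed(seed)
  total <- 0L
  rejected <- 0L
  recs <- lapply(GROUP_LEVELS, function(g) {
    p <- spec$params[[g]]
    n <- spec$cases_per_group[[g]]
    sz <- draw_case_sizes(p, n)
    rejected <<- rejected + sz$rejected
    total <<- total + n + sz$rejected
    pe_mu <- irregularity_to_form_pe(p$irregularity)
    pe_c <- rtrunc_norm(n, pe_mu, p$form_pe_sd, 0.2, 1.4)
    pe_n <- rtrunc_norm(n, pe_mu, p$form_pe_sd, 0.2, 1.4)
    data.frame(
      case_id = sprintf("syn_%s_%03d", g, seq_len(n)),
      group = g,
      cell_area = sz$cell_area,
      cell_perimeter = sqrt(4 * pi * sz$cell_area / pe_c),
      nuclear_area = sz$nuclear_area,
      nuclear_perimeter = sqrt(4 * pi * sz$nuclear_area / pe_n),
      stringsAsFactors = FALSE)
  })
  out <- validate_measurements(do.call(rbind, recs))
  attr(out, "rejected_fraction") <- rejected / total
  out
}

# Rasterize a closed polygon into mask[,] <- label at pixel centers inside.
rasterize_into <- function(mask, poly, label) {
  v <- poly_vertices(poly)
  xr <- range(v[, 1]); yr <- range(v[, 2])
  cs <- max(1L, floor(xr[1])):min(ncol(mask), ceiling(xr[2]))
  rs <- max(1L, floor(yr[1])):min(nrow(mask), ceiling(yr[2]))
  pts <- cbind(rep(cs, each = length(rs)), rep(rs, times = length(cs)))
  inside <- mgcv::in.out(v, pts)
  sel <- pts[inside, , drop = FALSE]
  mask[cbind(sel[, 2], sel[, 1])] <- label
  mask
}

# Generate one field: polygons, placement, rasters, per-object truth.
generate_field <- function(spec, p, case_sizes, case_id, field) {
  raster <- spec$raster
  cal <- spec$microns_per_pixel
  n_cells <- sample_range(spec$cells_per_field)
  margin <- 4
  cm <- matrix(0L, raster[1], raster[2])
  nm <- matrix(0L, raster[1], raster[2])
  placed <- list()
  truth <- list()
  for (i in seq_len(n_cells)) {
    area_um2 <- rtrunc_norm(1, case_sizes$cell_area,
                            spec$cell_cv * case_sizes$cell_area,
                            0.2 * case_sizes$cell_area, Inf)
    frac <- min(0.9, case_sizes$nuclear_area / case_sizes$cell_area)
    shape <- render_cell(area_um2 / cal^2, p$irregularity, frac)
    rmax <- max(sqrt((shape$cell[, 1])^2 + (shape$cell[, 2])^2))
    ok <- FALSE
    for (try in seq_len(200L)) {
      ctr <- c(stats::runif(1, 1 + margin + rmax, raster[2] - margin - rmax),
               stats::runif(1, 1 + margin + rmax, raster[1] - margin - rmax))
      clear <- TRUE
      for (q in placed) {
        if (sqrt(sum((ctr - q$ctr)^2)) < rmax + q$rmax + 2) { clear <- FALSE; break }
      }
      if (clear) { ok <- TRUE; break }
    }
    if (!ok) {
      bm_capacity_error(sprintf(
        "could not place cell %d of field %s/%d without overlap; raster too small",
        i, case_id, field))
    }
    cellv <- sweep(shape$cell, 2, ctr, `+`)
    nucv <- sweep(shape$nucleus, 2, ctr, `+`)
    cm <- rasterize_into(cm, cellv, i)
    nm <- rasterize_into(nm, nucv, i)
    placed[[length(placed) + 1L]] <- list(ctr = ctr, rmax = rmax)
    truth[[i]] <- data.frame(
      case_id = case_id, field = field, label = i,
      cell_area = polygon_area(cellv, cal),
      cell_perimeter = polygon_perimeter(cellv, cal),
      nuclear_area = polygon_area(nucv, cal),
      nuclear_perimeter = polygon_perimeter(nucv, cal))
  }
  # nuclei rasterized after cells could in principle overwrite a pixel of a
  # neighboring cell; placement margins prevent contact, so the nucleus
  # pixels are a subset of the cell's by construction
  list(pair = label_mask_pair(cm, nm, cal), truth = do.call(rbind, truth))
}

#' Generate a label-mask dataset (streaming)
#'
#' Walks the full design (groups, cases, fields) drawing per-case sizes as
#' in [generate_tabular()], rendering and placing 5-7 non-overlapping,
#' border-free cells per field, and either writes every field to `dir`
#' (16-bit TIFF masks + sidecar JSON, plus `ground_truth.csv` and
#' `manifest.json`) or hands each field to `field_callback` and discards
#' it, so arbitrarily large designs run in bounded memory. Deterministic
#' given the spec seed.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Output dataset directory, or `NULL` to skip writing.
#' @param seed Overrides `spec$seed` when given.
#' @param field_callback Optional `function(pair, case_id, group, field)`
#'   invoked on every generated field.
#' @return Data frame of ground-truth per-object polygon measurements
#'   (calibrated units), with attribute `"rejected_fraction"` as in
#'   [generate_tabular()].
#' @export
generate_dataset <- function(spec, dir = NULL, seed = spec$seed,
                             field_callback = NULL) {
  if (!inherits(spec, "synthetic_spec")) bm_config_error("spec must be a synthetic_spec")
  set.seed(seed)
  if (!is.null(dir)) dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  truth <- list()
  rejected <- 0L; total <- 0L
  for (g in GROUP_LEVELS) {
    p <- spec$params[[g]]
    for (i in seq_len(spec$cases_per_group[[g]])) {
      case_id <- sprintf("syn_%s_%03d", g, i)
      sz <- draw_case_sizes(p, 1L)
      rejected <- rejected + sz$rejected; total <- total + 1L + sz$rejected
      case_sizes <- list(cell_area = sz$cell_area, nuclear_area = sz$nuclear_area)
      n_fields <- sample_range(spec$fields_per_case)
      for (f in seq_len(n_fields)) {
        fl <- generate_field(spec, p, case_sizes, case_id, f)
        truth[[length(truth) + 1L]] <- fl$truth
        if (!is.null(dir)) write_mask_pair(fl$pair, dir, case_id, g, f)
        if (!is.null(field_callback)) field_callback(fl$pair, case_id, g, f)
      }
    }
  }
  truth <- do.call(rbind, truth)
  attr(truth, "rejected_fraction") <- rejected / total
  if (!is.null(dir)) {
    utils::write.csv(truth, file.path(dir, "ground_truth.csv"),
                     row.names = FALSE)
    jsonlite::write_json(spec_manifest(spec, seed), file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  truth
}

spec_manifest <- function(spec, seed) {
  list(generator = "basalmorph::generate_dataset",
       package_version = as.character(utils::packageVersion("basalmorph")),
       seed = seed,
       raster = spec$raster,
       microns_per_pixel = spec$microns_per_pixel,
       cases_per_group = as.list(spec$cases_per_group),
       fields_per_case = spec$fields_per_case,
       cells_per_field = spec$cells_per_field,
       cell_cv = spec$cell_cv,
       params = lapply(spec$params, function(p) unclass(p)))
}

#' Run the full synthetic pipeline in memory
#'
#' Generates the dataset field by field, measures each field immediately
#' ([measure_field()]), aggregates per case ([aggregate_case()]) and
#' returns the recovered measurement table; rasters are discarded after
#' measurement so the default 70-case design runs in bounded memory.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Overrides `spec$seed` when given.
#' @param max_cells_per_field Per-field cap passed to [aggregate_case()].
#' @return List with `records` (recovered per-case measurement table),
#'   `truth` (per-object ground-truth polygon measurements) and
#'   `rejected_fraction`.
#' @export
run_synthetic_pipeline <- function(spec, seed = spec$seed,
                                   max_cells_per_field = 7L) {
  fields <- new.env(parent = emptyenv())
  cb <- function(pair, case_id, group, field) {
    m <- measure_field(pair)
    key <- paste(group, case_id, sep = "\r")
    fields[[key]] <- c(fields[[key]], list(m))
  }
  truth <- generate_dataset(spec, dir = NULL, seed = seed, field_callback = cb)
  keys <- sort(ls(fields))
  recs <- do.call(rbind, lapply(keys, function(key) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    aggregate_case(fields[[key]], case_id = parts[2], group = parts[1],
                   max_cells_per_field = max_cells_per_field)
  }))
  list(records = validate_measurements(recs), truth = truth,
       rejected_fraction = attr(truth, "rejected_fraction"))
}
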