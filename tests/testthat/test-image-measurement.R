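test_that("polygon area and perimeter satisfy the basic geometric contract", {
  sq <- cbind(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))
  expect_equal(polygon_area(sq), 1)
  expect_equal(polygon_perimeter(sq), 4)
  # orientation invariance
  expect_equal(polygon_area(sq[4:1, ]), 1)
  # exact calibration homogeneity: area ~ cal^2, perimeter ~ cal
  expect_equal(polygon_area(sq, 2), 4)
  expect_equal(polygon_perimeter(sq, 2), 8)
  expect_equal(polygon_perimeter(sq, 0.1), 0.4)
  expect_error(polygon_area(cbind(c(0, 1), c(0, 0))),
               class = "bm_domain_error")
  expect_error(polygon_perimeter(cbind(c(0, 0, 0), c(0, 0, 0))),
               class = "bm_domain_error")
})

test_that("contour extraction recovers rectangles within discretization tolerance", {
  m <- matrix(0L, 40, 60)
  m[11:30, 16:45] <- 1L   # 20 x 30 px rectangle
  ct <- extract_contours(m)
  expect_length(ct, 1L)
  expect_equal(ct[[1]]$label, 1L)
  # smoothing rounds the sharp corners slightly: area within 2%,
  # perimeter within 6% for a rectangle (the estimator targets smooth
  # biological outlines, where it is far more accurate; see disk test)
  expect_equal(polygon_area(ct[[1]]), 600, tolerance = 0.02)
  expect_equal(polygon_perimeter(ct[[1]]), 100, tolerance = 0.06)
  # closed polygon in pixel-center coordinates
  v <- ct[[1]]$vertices
  expect_identical(v[1, ], v[nrow(v), ])
  expect_true(all(v[, "x"] >= 15 & v[, "x"] <= 46))
  expect_true(all(v[, "y"] >= 10 & v[, "y"] <= 31))
})

test_that("disk measurements converge to analytic values (area 1%, perimeter 2%)", {
  for (r in c(50, 80)) {
    ct <- extract_contours(disk_mask(r))
    expect_equal(polygon_area(ct[[1]]), pi * r^2, tolerance = 0.01)
    expect_equal(polygon_perimeter(ct[[1]]), 2 * pi * r, tolerance = 0.02)
  }
  # calibrated: radius 50 px at 0.1 um/px is a 5 um disk
  ct <- extract_contours(disk_mask(50))
  expect_equal(polygon_area(ct[[1]], 0.1), pi * 25, tolerance = 0.01)
  expect_equal(polygon_perimeter(ct[[1]], 0.1), 2 * pi * 5, tolerance = 0.02)
  # pixel-count oracle agrees with the polygon area
  expect_equal(polygon_area(ct[[1]]), sum(disk_mask(50) > 0), tolerance = 0.01)
})

test_that("multiple labels, empty masks, disconnected and holed objects", {
  expect_length(extract_contours(matrix(0L, 10, 10)), 0L)

  m <- matrix(0L, 90, 150)
  m[11:40, 11:60] <- 3L     # 30 x 50
  m[51:80, 81:140] <- 7L    # 30 x 60
  ct <- extract_contours(m)
  expect_equal(vapply(ct, `[[`, integer(1), "label"), c(3L, 7L))
  expect_equal(polygon_area(ct[[1]]), sum(m == 3L), tolerance = 0.03)
  expect_equal(polygon_area(ct[[2]]), sum(m == 7L), tolerance = 0.03)

  # disconnected label: skipped with a logged reason, other labels kept
  md <- matrix(0L, 60, 60)
  md[5:15, 5:15] <- 1L
  md[40:50, 40:50] <- 1L
  md[20:35, 20:35] <- 2L
  expect_warning(ctd <- extract_contours(md), "disconnected")
  expect_equal(vapply(ctd, `[[`, integer(1), "label"), 2L)
  expect_equal(attr(ctd, "skipped")$label, 1L)

  # object with a hole
  mh <- matrix(0L, 40, 40)
  mh[10:30, 10:30] <- 1L
  mh[18:22, 18:22] <- 0L
  expect_warning(cth <- extract_contours(mh), "holes")
  expect_length(cth, 0L)

  expect_error(extract_contours(matrix(-1L, 3, 3)), class = "bm_domain_error")
})

test_that("measure_field measures complete cell/nucleus pairs in microns", {
  # centered ellipse cell (semi-axes 20 x 15 px) with concentric nucleus
  # (10 x 7.5 px) at 0.25 um/px
  cm <- ellipse_mask(20, 15, pad = 10L)
  nr <- nrow(cm); nc <- ncol(cm)
  ctr_r <- (nr + 1) / 2; ctr_c <- (nc + 1) / 2
  cc <- matrix(rep(seq_len(nc), each = nr), nr)
  rr <- matrix(rep(seq_len(nr), times = nc), nr)
  nm <- matrix(as.integer(((cc - ctr_c)^2 / 10^2 + (rr - ctr_r)^2 / 7.5^2) <= 1),
               nr, nc)
  pair <- label_mask_pair(cm, nm, 0.25)
  m <- measure_field(pair)
  expect_equal(nrow(m), 1L)
  expect_equal(m$cell_area, pi * 20 * 15 * 0.0625, tolerance = 0.02)
  expect_equal(m$nuclear_area, pi * 10 * 7.5 * 0.0625, tolerance = 0.02)
  expect_equal(m$nuclear_area / m$cell_area, 0.25, tolerance = 0.02)
  expect_lt(m$nuclear_area, m$cell_area)

  # border-touching cell: excluded, zero rows
  cmb <- cm; cmb[1, 30:40] <- 1L
  mb <- measure_field(label_mask_pair(cmb, nm, 0.25))
  expect_equal(nrow(mb), 0L)
  expect_match(attr(mb, "excluded")$reason, "border")

  # cell without nucleus: excluded with its own reason
  mn <- measure_field(label_mask_pair(cm, nm * 0L, 0.25))
  expect_equal(nrow(mn), 0L)
  expect_match(attr(mn, "excluded")$reason, "no nucleus")

  # empty masks
  me <- measure_field(label_mask_pair(cm * 0L, nm * 0L, 0.25))
  expect_equal(nrow(me), 0L)
})

test_that("label_mask_pair enforces co-registration invariants", {
  cm <- disk_mask(10)
  nm <- disk_mask(5, pad = 13L)
  expect_s3_class(label_mask_pair(cm, nm, 0.2), "label_mask_pair")
  expect_error(label_mask_pair(cm, nm[-1, ], 0.2), "dimensions",
               class = "bm_domain_error")
  expect_error(label_mask_pair(cm, nm * 2L, 0.2), "matching cell",
               class = "bm_domain_error")
  nm_out <- cm * 0L
  nm_out[1:3, 1:3] <- 1L   # nucleus pixels outside the cell
  expect_error(label_mask_pair(cm, nm_out, 0.2), "outside",
               class = "bm_domain_error")
  expect_error(label_mask_pair(cm, nm, -1), class = "bm_domain_error")
})

test_that("aggregate_case keeps the largest cells per field then averages", {
  f1 <- data.frame(label = 1:10, cell_area = 10 * (1:10),
                   cell_perimeter = 1:10, nuclear_area = 1:10,
                   nuclear_perimeter = (1:10) / 2)
  rec <- aggregate_case(list(f1), "case", "scc", max_cells_per_field = 7L)
  # exactly the 7 largest by cell area contribute
  expect_equal(rec$cell_area, mean(10 * (4:10)))
  expect_equal(rec$nuclear_area, mean(4:10))
  expect_equal(rec$nuclear_perimeter, mean((4:10) / 2))

  # two fields of identical single objects: record equals the object
  obj <- data.frame(label = 1L, cell_area = 120, cell_perimeter = 44,
                    nuclear_area = 55, nuclear_perimeter = 28)
  rec2 <- aggregate_case(list(obj, obj), "c2", "leukoplakia")
  expect_equal(unlist(rec2[, c("cell_area", "cell_perimeter",
                               "nuclear_area", "nuclear_perimeter")],
                      use.names = FALSE),
               c(120, 44, 55, 28))

  # hand-computed two-field mean
  f2 <- obj; f2$cell_area <- 100; f2$nuclear_area <- 45
  rec3 <- aggregate_case(list(obj, f2), "c3", "normal")
  expect_equal(rec3$cell_area, 110)
  expect_equal(rec3$nuclear_area, 50)

  empty <- f1[0, ]
  expect_error(aggregate_case(list(empty), "c4", "scc"),
               class = "bm_data_error")
})

test_that("mask pairs round-trip through 16-bit TIFF and sidecar JSON", {
  dir <- tempfile("ds")
  on.exit(unlink(dir, recursive = TRUE))
  cm <- disk_mask(12, label = 3L)
  nm <- disk_mask(6, pad = 14L, label = 3L)
  pair <- label_mask_pair(cm, nm, 0.25)
  sidecar <- write_mask_pair(pair, dir, "caseA", "scc", 2L)
  back <- read_mask_pair(sidecar)
  expect_identical(back$pair$cell_mask, cm)
  expect_identical(back$pair$nucleus_mask, nm)
  expect_equal(back$pair$microns_per_pixel, 0.25)
  expect_equal(back$case_id, "caseA")
  expect_equal(back$field, 2L)
  expect_error(read_mask_pair(file.path(dir, "nope.json")),
               class = "bm_io_error")
})
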