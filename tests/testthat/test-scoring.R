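# minimal labelled segmentation around a given label matrix
fake_seg <- function(labels) {
  seg <- new_nuclei_segmentation(labels > 0, matrix(FALSE, nrow(labels),
                                                    ncol(labels)))
  seg$labels <- labels
  seg
}

fake_mask <- function(marker, mask) {
  structure(list(marker = marker, mask = mask, min_component_size = 0,
                 restricted_to_nuclei = FALSE, threshold = NA_real_),
            class = "marker_mask")
}

test_that("perinuclear zones are rings disjoint from their nuclei", {
  lab <- matrix(0L, 64, 64)
  lab[disk_mask(64, 64, 32, 32, 8)] <- 1L
  z <- perinuclear_zones(fake_seg(lab), ring_width = 3)
  expect_error(perinuclear_zones(fake_seg(lab), ring_width = 0), "ring_width")
  zone <- z$zone_labels == 1L
  expect_false(any(zone & lab > 0))
  expect_gt(sum(zone), 0)
  # every zone pixel within chessboard distance 3 of the nucleus
  d <- which(zone, arr.ind = TRUE)
  n <- which(lab > 0, arr.ind = TRUE)
  cheb <- apply(d, 1, function(p)
    min(pmax(abs(n[, 1] - p[1]), abs(n[, 2] - p[2]))))
  expect_true(all(cheb >= 1 & cheb <= 3))
})

test_that("overlapping zones partition to the nearer nucleus, ties low id", {
  lab <- matrix(0L, 64, 64)
  lab[disk_mask(64, 64, 32, 20, 8)] <- 1L
  lab[disk_mask(64, 64, 32, 38, 8)] <- 2L    # 2 px apart
  z <- perinuclear_zones(fake_seg(lab), ring_width = 3)
  zl <- z$zone_labels
  expect_true(all(zl[lab > 0] == 0L))
  # brute force: chessboard distance to each nucleus; nearer wins, tie -> 1
  px <- which(zl > 0, arr.ind = TRUE)
  n1 <- which(lab == 1L, arr.ind = TRUE); n2 <- which(lab == 2L, arr.ind = TRUE)
  for (i in seq_len(nrow(px))) {
    d1 <- min(pmax(abs(n1[, 1] - px[i, 1]), abs(n1[, 2] - px[i, 2])))
    d2 <- min(pmax(abs(n2[, 1] - px[i, 1]), abs(n2[, 2] - px[i, 2])))
    want <- if (d1 < d2) 1L else if (d2 < d1) 2L else 1L
    expect_identical(zl[px[i, 1], px[i, 2]], want)
  }
  # distant nuclei: rings disjoint by construction (single-valued labels)
  lab2 <- matrix(0L, 64, 64)
  lab2[disk_mask(64, 64, 16, 16, 6)] <- 1L
  lab2[disk_mask(64, 64, 48, 48, 6)] <- 2L
  z2 <- perinuclear_zones(fake_seg(lab2), 3)
  expect_setequal(unique(as.vector(z2$zone_labels)), c(0L, 1L, 2L))
})

test_that("the 1% positivity rule is inclusive and monotone", {
  # a zone of exactly 200 px, constructed directly
  lab <- matrix(0L, 40, 40)
  lab[20, 20] <- 1L
  seg <- fake_seg(lab)
  zone <- matrix(0L, 40, 40)
  zone[5:12, 5:29][seq_len(200)] <- 1L   # 200 zone pixels
  zones <- structure(list(zone_labels = zone, ring_width = 3, labels = 1L),
                     class = "perinuclear_zones")
  mask2 <- matrix(FALSE, 40, 40); mask2[5:6, 5] <- TRUE   # 2 / 200 = 1.0%
  mask1 <- matrix(FALSE, 40, 40); mask1[5, 5] <- TRUE     # 1 / 200 = 0.5%
  pos2 <- call_cells(seg, zones, list(fake_mask("th", mask2)),
                     min_cells = 0)$calls$positive
  pos1 <- call_cells(seg, zones, list(fake_mask("th", mask1)),
                     min_cells = 0)$calls$positive
  expect_true(pos2)
  expect_false(pos1)
  # full-cover positive, empty negative
  full <- call_cells(seg, zones, list(fake_mask("th", zone > 0)),
                     min_cells = 0)
  expect_true(full$calls$positive)
  none <- call_cells(seg, zones, list(fake_mask("th", matrix(FALSE, 40, 40))),
                     min_cells = 0)
  expect_false(none$calls$positive)
  # monotonicity: lowering the threshold never loses positives
  thr <- c(0.10, 0.05, 0.01, 0.005)
  counts <- sapply(thr, function(t)
    sum(call_cells(seg, zones, list(fake_mask("th", mask1)),
                   min_fraction = t, min_cells = 0)$calls$positive))
  expect_true(all(diff(counts) >= 0))
  # shape mismatch rejected
  expect_error(call_cells(seg, zones, list(fake_mask("th",
    matrix(FALSE, 10, 10)))), "shape")
})

test_that("per-image call counts satisfy the set identities", {
  for (s in 1:3) {
    sec <- generate_section(synth_params(n_cells = 36,
                                         image_shape = c(288, 288),
                                         seed = 20 + s))
    fx <- image_features(sec$image)
    cc <- fx$features
    expect_lte(cc$th_foxa2_cell_fraction, cc$th_cell_fraction + 1e-12)
    expect_lte(cc$th_foxa2_cell_fraction, cc$foxa2_cell_fraction + 1e-12)
    expect_equal(cc$th_neg_foxa2_cell_fraction,
                 cc$foxa2_cell_fraction - cc$th_foxa2_cell_fraction)
    expect_lte(cc$th_foxa2_px_fraction,
               min(cc$th_px_fraction, cc$foxa2_px_fraction) + 1e-12)
  }
})

test_that("pixel fractions normalize by the Hoechst mask", {
  nuc <- matrix(FALSE, 50, 50); nuc[11:30, 11:30] <- TRUE
  seg <- new_nuclei_segmentation(nuc, matrix(FALSE, 50, 50))
  same <- fake_mask("foxa2", nuc)
  half <- nuc; half[11:30, 21:30] <- FALSE
  pf <- pixel_fractions(list(same, fake_mask("th", half)), seg)
  expect_equal(pf$fractions$foxa2, 1.0)
  expect_equal(pf$fractions$th, 0.5)
  expect_equal(pf$fractions$th_foxa2, 0.5)
  expect_equal(pf$fractions$foxa2_not_th, 0.5)
  none <- pixel_fractions(list(fake_mask("th", matrix(FALSE, 50, 50))), seg)
  expect_equal(none$fractions$th, 0)
  # empty nuclei mask flags the image
  seg0 <- new_nuclei_segmentation(matrix(FALSE, 50, 50),
                                  matrix(FALSE, 50, 50))
  pf0 <- pixel_fractions(list(same), seg0)
  expect_true(pf0$flagged)
  expect_true(is.na(pf0$fractions$foxa2))
})

test_that("TH+ cell fractions track ground truth on generated sections", {
  errs <- sapply(1:5, function(s) {
    sec <- generate_section(synth_params(n_cells = 48,
                                         image_shape = c(320, 320),
                                         seed = 40 + s))
    fx <- image_features(sec$image)
    fx$features$th_cell_fraction - sec$truth$totals$th_fraction
  })
  expect_true(all(abs(errs) <= 0.05))
})
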