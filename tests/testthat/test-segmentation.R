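test_that("an all-zero Hoechst channel yields empty masks, not an error", {
  img <- image_stack(list(hoechst = matrix(0, 64, 64)))
  seg <- segment_nuclei(img)
  expect_false(any(seg$nuclei_mask))
  expect_false(any(seg$pyknotic_mask))
  expect_error(segment_nuclei(image_stack(list(hoechst = matrix(NaN, 8, 8)))),
               "non-finite")
})

test_that("nuclei and pyknotic masks are always disjoint", {
  for (s in 1:3) {
    sec <- generate_section(synth_params(n_cells = 30,
                                         image_shape = c(256, 256),
                                         pyknotic_fraction = 0.2, seed = s))
    seg <- segment_nuclei(sec$image)
    expect_false(any(seg$nuclei_mask & seg$pyknotic_mask))
  }
})

test_that("pyknotic nuclei are recovered and normal nuclei untouched", {
  p <- synth_params(n_cells = 22, pyknotic_fraction = 2 / 22,
                    image_shape = c(256, 256), seed = 3)
  sec <- generate_section(p)
  tr <- sec$truth
  seg <- segment_nuclei(sec$image)
  for (i in which(tr$cells$pyknotic))
    expect_gte(mean(seg$pyknotic_mask[tr$nucleus_pixels[[i]]]), 0.5)
  normal_px <- unlist(tr$nucleus_pixels[!tr$cells$pyknotic])
  expect_lt(mean(seg$pyknotic_mask[normal_px]), 0.05)
  expect_gte(mean(seg$nuclei_mask[normal_px]), 0.9)
})

test_that("small-component removal honors the strict cutoff", {
  m <- matrix(FALSE, 60, 120)
  m[6:14, 6:16] <- TRUE       # 9 x 11 = 99 px
  m[30:39, 30:39] <- TRUE     # 10 x 10 = 100 px
  m[6:20, 80:89] <- TRUE      # 150 px
  out <- remove_small_components(m, 100)
  expect_false(any(out[6:14, 6:16]))
  expect_true(all(out[30:39, 30:39]))
  expect_true(all(out[6:20, 80:89]))
})

test_that("marker masks apply median, threshold, removal and restriction", {
  ch <- matrix(0, 80, 160)
  ch[6:14, 6:16] <- 0.9       # 99 px -> removed
  ch[30:44, 30:39] <- 0.9     # 150 px -> kept
  img <- image_stack(list(hoechst = matrix(0, 80, 160), foxa2 = ch))
  p <- seg_params(median_radius = 0,
                  thresholds = list(default = list(method = "fixed",
                                                   value = 0.5)))
  mm <- marker_mask(img, "foxa2", p)
  expect_false(any(mm$mask[6:14, 6:16]))
  expect_true(all(mm$mask[30:44, 30:39]))
  expect_error(marker_mask(img, "nestin", p), "unknown marker role")

  # restriction: a blob entirely outside the nuclei mask vanishes
  seg <- new_nuclei_segmentation(matrix(FALSE, 80, 160),
                                 matrix(FALSE, 80, 160))
  seg$nuclei_mask[60:70, 100:120] <- TRUE
  mm2 <- marker_mask(img, "foxa2", p, nuclei = seg)
  expect_true(mm2$restricted_to_nuclei)
  expect_false(any(mm2$mask))
})

test_that("nucleus size exclusion is strict at 10,000 pixels", {
  mk <- matrix(FALSE, 140, 140)
  mk[21:120, 21:120] <- TRUE                 # exactly 10,000 px
  seg <- new_nuclei_segmentation(mk, matrix(FALSE, 140, 140))
  lab <- label_nuclei(seg, seg_params())
  expect_equal(length(retained_labels(lab)), 1L)
  expect_length(lab$removed_oversize_ids, 0)

  mk[121, 21] <- TRUE                        # 10,001 px
  seg2 <- new_nuclei_segmentation(mk, matrix(FALSE, 140, 140))
  lab2 <- label_nuclei(seg2, seg_params())
  expect_equal(length(retained_labels(lab2)), 0L)
  expect_length(lab2$removed_oversize_ids, 1)
})

test_that("watershed separates touching disks into single nuclei", {
  m <- disk_mask(64, 64, 32, 24, 10) | disk_mask(64, 64, 32, 40, 10)
  seg <- new_nuclei_segmentation(m, matrix(FALSE, 64, 64))
  lab <- label_nuclei(seg, seg_params())
  expect_equal(length(retained_labels(lab)), 2L)
  expect_true(all(lab$labels[!m] == 0L))     # labels subset of the mask
})

test_that("mask area is monotone in component cutoff and threshold", {
  set.seed(21)
  for (trial in 1:5) {
    ch <- matrix(runif(64 * 64), 64, 64)
    ch <- gaussian_blur_cpp(ch, 2)
    img <- image_stack(list(hoechst = matrix(0, 64, 64), cc3 = ch))
    thr_seq <- quantile(ch, c(0.5, 0.7, 0.9))
    areas <- sapply(thr_seq, function(v) sum(marker_mask(img, "cc3",
      seg_params(median_radius = 0, min_component_size = 1,
                 thresholds = list(default = list(method = "fixed",
                                                  value = v))))$mask))
    expect_true(all(diff(areas) <= 0))
    mask <- ch > thr_seq[2]
    sizes <- c(1, 5, 20, 60)
    areas2 <- sapply(sizes, function(k) sum(remove_small_components(mask, k)))
    expect_true(all(diff(areas2) <= 0))
  }
})

test_that("component labelling agrees with a brute-force flood fill", {
  set.seed(77)
  for (trial in 1:20) {
    m <- matrix(runif(64 * 64) < 0.35, 64, 64)
    for (conn in c(4, 8)) {
      got <- label_components(m, conn)
      want <- oracle_components(m, conn)
      expect_equal(max(got), max(want))
      # identical partitions (labels may differ only by naming; both use
      # column-major first-touch order, so they are equal outright)
      expect_identical(got, want)
    }
  }
})

test_that("retained label count tracks the true viable cell count", {
  for (s in 1:3) {
    sec <- generate_section(synth_params(n_cells = 40,
                                         image_shape = c(288, 288),
                                         seed = s))
    seg <- label_nuclei(segment_nuclei(sec$image), seg_params())
    n_true <- sec$truth$totals$n_viable
    expect_lt(abs(length(retained_labels(seg)) - n_true) / n_true, 0.1)
  }
})
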