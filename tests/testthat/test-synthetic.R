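test_that("empty and zero-fraction sections are clean", {
  p <- synth_params(n_cells = 0, seed = 3)
  sec <- generate_section(p)
  expect_equal(sec$truth$totals$n_cells, 0)
  expect_equal(sec$truth$totals$n_nodes, 0)
  expect_equal(sec$truth$totals$n_links, 0)
  # Hoechst is pure noise: no pixel anywhere near nuclear intensity
  expect_lt(max(sec$image$channels$hoechst), 0.25)

  p2 <- synth_params(n_cells = 30, image_shape = c(256, 256),
                     marker_profiles = list(
                       marker_profile("th", 0, "cytoplasmic+neurite"),
                       marker_profile("foxa2", 0.7, "nuclear")),
                     seed = 4)
  sec2 <- generate_section(p2)
  expect_equal(sec2$truth$totals$th_fraction, 0)
  expect_lt(max(sec2$image$channels$th), 0.25)
})

test_that("generation is a pure function of the parameter set", {
  p <- synth_params(n_cells = 40, image_shape = c(256, 256), seed = 11)
  a <- generate_section(p)
  b <- generate_section(p)
  expect_identical(a$image$channels, b$image$channels)
  expect_identical(a$truth, b$truth)
  p$seed <- 12L
  c <- generate_section(p)
  expect_false(identical(a$image$channels$hoechst, c$image$channels$hoechst))
})

test_that("per-image totals equal aggregation of per-cell records", {
  for (s in c(1, 7)) {
    sec <- generate_section(synth_params(n_cells = 60,
                                         image_shape = c(320, 320),
                                         seed = s), render = FALSE)
    expect_null(sec$truth$nucleus_pixels)
    cells <- sec$truth$cells
    tt <- sec$truth$totals
    viable <- !cells$pyknotic
    expect_identical(tt$n_viable, sum(viable))
    expect_equal(tt$th_fraction, sum(cells$th & viable) / sum(viable))
    expect_equal(tt$th_neg_foxa2_count, sum(!cells$th & cells$foxa2 & viable))
    expect_equal(tt$th_foxa2_fraction + tt$th_neg_foxa2_fraction,
                 tt$foxa2_fraction)
    expect_identical(tt$n_nodes, sum(cells$n_nodes))
    expect_identical(tt$n_links, sum(cells$n_links))
  }
})

test_that("cohort manifests follow the factor design", {
  specs <- pd_cohort_design(n_sections = 2)
  cohort <- generate_cohort(specs, base = synth_params(
    n_cells = 10, image_shape = c(160, 160), seed = 1), render = FALSE)
  expect_equal(nrow(cohort$manifest), 4 * 3 * 2)
  expect_setequal(unique(cohort$manifest$group),
                  c("H", "P", "H-G2019S", "P-GC"))
  expect_false(anyDuplicated(cohort$manifest$section_id) > 0)

  empty <- generate_cohort(list(), base = synth_params(), render = FALSE)
  expect_equal(nrow(empty$manifest), 0)

  dup <- list(cohort_group("H", 10, 2), cohort_group("H", 10, 2))
  expect_error(generate_cohort(dup, base = synth_params(
    n_cells = 5, image_shape = c(160, 160), seed = 1), render = FALSE),
    "duplicate")
})

test_that("a marker-fraction delta shifts the group mean by the delta", {
  base <- synth_params(n_cells = 48, image_shape = c(288, 288), seed = 5)
  specs <- list(
    cohort_group("A", 35, 20),
    cohort_group("B", 35, 20,
                 deltas = list(marker_fractions = list(th = 0.275))))
  ft <- truth_features(generate_cohort(specs, base, render = FALSE))
  mA <- mean(ft$th_cell_fraction[ft$group == "A"])
  mB <- mean(ft$th_cell_fraction[ft$group == "B"])
  # binomial + section-jitter oracle for the SE of a 20-section group mean
  se <- sqrt((0.5 * 0.5 / 44 + 0.03^2) / 20)
  expect_lt(abs(mA - 0.55), 4 * se)
  expect_lt(abs(mB - 0.275), 4 * se)
  expect_gt(mA - mB, 0.275 - 8 * se)
})

test_that("impossible packings are rejected, feasible dense ones are not", {
  expect_error(generate_section(synth_params(n_cells = 500,
                                             image_shape = c(256, 256))),
               "infeasible packing")
  expect_silent(generate_section(synth_params(n_cells = 10,
                                              image_shape = c(160, 160),
                                              seed = 2), render = FALSE))
})

test_that("nuclei do not overlap and stay inside the image", {
  sec <- generate_section(synth_params(n_cells = 60,
                                       image_shape = c(320, 320), seed = 9))
  px <- unlist(sec$truth$nucleus_pixels)
  expect_equal(anyDuplicated(px), 0L)
  expect_true(all(px >= 1 & px <= 320 * 320))
})
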