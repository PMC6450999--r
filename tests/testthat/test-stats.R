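test_that("F statistics equal the textbook decomposition on balanced data", {
  for (seed in c(1, 2, 3)) {
    df <- balanced_toy(seed, g = c("H", "P", "H-G2019S"), r = 5)
    res <- two_way_anova(df, "y")
    want <- oracle_balanced_anova(df$y, df$group, df$day)
    got <- setNames(res$table$statistic, res$table$term)
    expect_equal(unname(got["group"]), unname(want$F["A"]), tolerance = 1e-9)
    expect_equal(unname(got["day"]), unname(want$F["B"]), tolerance = 1e-9)
    expect_equal(unname(got["group:day"]), unname(want$F["AB"]),
                 tolerance = 1e-9)
    # SS decomposition adds to the total on balanced designs
    expect_equal(sum(res$table$sumsq), sum((df$y - mean(df$y))^2),
                 tolerance = 1e-9)
  }
})

test_that("degenerate inputs are handled as specified", {
  df <- balanced_toy(4)
  # constant feature: flagged, no test
  df$flat <- 1
  expect_true(two_way_anova(df, "flat")$flagged)
  # values identical across days within (group, replicate): SS_day == 0
  set.seed(5)
  rep_effect <- rnorm(length(unique(interaction(df$group, df$rep))))
  names(rep_effect) <- unique(as.character(interaction(df$group, df$rep)))
  df$y2 <- rep_effect[as.character(interaction(df$group, df$rep))]
  res <- two_way_anova(df, "y2")
  expect_equal(res$table$sumsq[res$table$term == "day"], 0)
  # single-level factor rejected
  df1 <- df[df$group == "H", ]
  expect_error(two_way_anova(df1, "y"), "2 levels")
  # empty cell: interaction dropped with a warning
  df2 <- df[!(df$group == "P" & df$day == 35), ]
  expect_warning(res2 <- two_way_anova(df2, "y"), "interaction dropped")
  expect_false("group:day" %in% res2$table$term)
})

test_that("Tukey-adjusted p-values never undercut unadjusted ones", {
  set.seed(9)
  df <- expand.grid(group = c("H", "P", "H-G2019S", "P-GC"),
                    day = c(10, 35, 70), rep = 1:5)
  df <- df[-c(1, 10, 25), ]   # unbalanced
  df$y <- rnorm(nrow(df), 2 + 0.3 * (df$group == "P") * (df$day > 10))
  df$line <- "L"; df$section_id <- seq_len(nrow(df))
  res <- two_way_anova(df, "y")
  expect_true(all(res$tukey$p_adj >= res$tukey$p_unadj - 1e-12))
  expect_true(all(res$tukey$p_adj >= 0 & res$tukey$p_adj <= 1))
  expect_equal(nrow(res$tukey), 6 * 3)   # all pairs within each day
})

test_that("heatmap matrix is z-scored and clustering is deterministic", {
  base <- synth_params(n_cells = 20, image_shape = c(224, 224), seed = 2)
  cohort <- generate_cohort(pd_cohort_design(n_sections = 4), base,
                            render = FALSE)
  ft <- truth_features(cohort)
  hm <- suppressMessages(cluster_heatmap(ft))
  expect_equal(unname(rowMeans(hm$matrix)), rep(0, nrow(hm$matrix)),
               tolerance = 1e-12)
  expect_equal(unname(apply(hm$matrix, 1, sd)), rep(1, nrow(hm$matrix)),
               tolerance = 1e-12)
  hm2 <- suppressMessages(cluster_heatmap(ft))
  expect_identical(hm$row_hclust$merge, hm2$row_hclust$merge)
  expect_identical(hm$col_hclust$order, hm2$col_hclust$order)
  # identical feature rows merge first at height 0
  ft$dup1 <- ft$th_cell_fraction
  ft$dup2 <- ft$th_cell_fraction
  hm3 <- suppressMessages(cluster_heatmap(ft))
  expect_equal(min(hm3$row_hclust$height), 0)
  # all-constant tables are rejected
  ftc <- ft; for (f in setdiff(names(ftc), c("line", "group", "day",
                                             "section_id"))) ftc[[f]] <- 1
  expect_error(suppressMessages(cluster_heatmap(ftc)), "constant")
})

test_that("a dominant day effect groups heatmap columns by day", {
  base <- synth_params(n_cells = 40, image_shape = c(288, 288), seed = 6)
  specs <- list()
  for (g in c("H", "P", "H-G2019S", "P-GC")) for (d in c(10, 35)) {
    specs[[length(specs) + 1L]] <- cohort_group(
      g, d, 6, deltas = if (d == 35)
        list(marker_fractions = list(th = 0.85, foxa2 = 0.40)) else list())
  }
  ft <- truth_features(generate_cohort(specs, base, render = FALSE))
  hm <- suppressMessages(cluster_heatmap(ft))
  day_of <- as.numeric(sub(".*_d", "", colnames(hm$matrix)))
  split2 <- stats::cutree(hm$col_hclust, k = 2)
  expect_equal(length(unique(tapply(split2, day_of, function(v)
    paste(sort(unique(v)), collapse = "")))), 2)
})

test_that("feature assembly averages fields and logs exclusions", {
  man <- data.frame(path = NA, line = "L", group = "H", day = 10,
                    section_id = rep(c("s1", "s2"), c(3, 1)))
  per <- list(`s1:1` = list(th_px_fraction = 0.2),
              `s1:2` = list(th_px_fraction = 0.4),
              `s1:3` = list(th_px_fraction = 0.6))
  ft <- assemble_features(man, per)
  expect_equal(nrow(ft), 1)
  expect_equal(ft$th_px_fraction, 0.4)
  expect_equal(attr(ft, "exclusions")$section_id, "s2")
  expect_error(assemble_features(man, list()), "no sections")
})

test_that("the phenotype report summarizes means, SEMs and contrasts", {
  df <- balanced_toy(11, g = c("H", "P"), d = c(10, 35), r = 6)
  res <- list(y = two_way_anova(df, "y"))
  rep <- phenotype_report(df, res)
  s <- rep$y$summary
  expect_setequal(names(s), c("group", "day", "n", "mean", "sem"))
  h10 <- df$y[df$group == "H" & df$day == 10]
  expect_equal(s$mean[s$group == "H" & s$day == 10], mean(h10))
  expect_equal(s$sem[s$group == "H" & s$day == 10],
               sd(h10) / sqrt(length(h10)))
  expect_true(all(rep$y$tukey$stars %in% c("ns", "*", "**", "***", "****")))
  empty <- phenotype_report(df, list())
  expect_length(empty, 0)
})
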