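#' Type-I error of the phenotyping ANOVA under the null
#'
#' Simulates cohorts with no group effect anywhere (the generator's
#' ground-truth features, no image rendering — isolating the statistical
#' calibration from segmentation noise) and reports how often the
#' genotype main effect is declared significant.
#'
#' @param n_sim number of null cohorts.
#' @param n_sections sections per group x day cell.
#' @param base base [synth_params()] (n_cells may be reduced for speed).
#' @param feature feature tested.
#' @param alpha significance level.
#' @param seed integer seed.
#' @return list: `rate` (rejection fraction), `n_sim`, `p_values`.
#' @export
null_rejection_rate <- function(n_sim = 200, n_sections = 8,
                                base = synth_params(n_cells = 48,
                                                    image_shape = c(288, 288)),
                                feature = "th_cell_fraction",
                                alpha = 0.05, seed = 1) {
  p_values <- numeric(n_sim)
  for (s in seq_len(n_sim)) {
    b <- base
    b$seed <- as.integer((seed + 7919 * s) %% 2147483647)
    cohort <- generate_cohort(
      pd_cohort_design(n_sections = n_sections, null_cohort = TRUE),
      base = b, render = FALSE)
    ft <- truth_features(cohort)
    res <- two_way_anova(ft, feature)
    p_values[s] <- res$table$p_value[res$table$term == "group"]
  }
  list(rate = mean(p_values < alpha), n_sim = n_sim, p_values = p_values)
}

#' Power and specificity of the phenotype readouts at the study design
#'
#' Repeats the disease-cohort simulation (patient-type deficits injected at
#' days 35/70 only) and records, per repeat and feature, whether the
#' healthy-vs-patient Tukey comparison is significant at each day. The
#' expected pattern at the study's per-group section counts is:
#' day-10 comparisons non-significant, day-35 comparisons significant.
#'
#' @param n_repeats simulation repeats.
#' @param n_sections sections per group x day cell.
#' @param base base [synth_params()].
#' @param days days simulated (the tested contrast needs 10 and 35).
#' @param groups genotype groups simulated.
#' @param level "image" runs the full image-analysis pipeline per section;
#'   "truth" uses the generator's ground-truth features.
#' @param features features tested; defaults depend on `level` (pixel-signal
#'   readouts for "image", cell-fraction readouts for "truth").
#' @param contrast Tukey contrast inspected (healthy vs patient).
#' @param alpha significance level.
#' @param config [pipeline_config()] for `level = "image"`.
#' @param effect injected patient-group effect, see [pd_cohort_design()].
#' @param seed integer seed.
#' @return list with `per_feature`: data.frame (feature, day10_sig_rate,
#'   day35_sig_rate) and the raw significance matrix `sig`.
#' @export
power_study <- function(n_repeats = 50, n_sections = 20,
                        base = synth_params(n_cells = 28,
                                            image_shape = c(224, 224)),
                        days = c(10, 35),
                        groups = c("H", "P"),
                        level = c("image", "truth"),
                        features = NULL,
                        contrast = "H - P",
                        alpha = 0.05,
                        config = pipeline_config(),
                        effect = list(th_fraction = 0.35,
                                      foxa2_fraction = 0.75,
                                      bifurcation_prob = 0.25),
                        seed = 1) {
  level <- match.arg(level)
  if (is.null(features))
    features <- if (level == "image")
      c("th_foxa2_px_fraction", "n_nodes", "foxa2_not_th_px_fraction")
    else c("th_foxa2_cell_fraction", "n_nodes", "th_neg_foxa2_cell_fraction")
  sig <- array(NA, dim = c(n_repeats, length(features), 2),
               dimnames = list(NULL, features, c("d10", "d35")))
  for (r in seq_len(n_repeats)) {
    b <- base
    b$seed <- as.integer((seed + 104729 * r) %% 2147483647)
    design <- pd_cohort_design(n_sections = n_sections, groups = groups,
                               days = days,
                               affected = intersect(c("P", "H-G2019S"),
                                                    groups),
                               effect = effect)
    cohort <- generate_cohort(design, base = b,
                              render = level == "image")
    ft <- if (level == "image")
      run_pipeline(cohort$manifest, config, images = cohort$images)$features
    else truth_features(cohort)
    for (f in features) {
      res <- two_way_anova(ft, f)
      if (res$flagged) next
      tk <- res$tukey[res$tukey$contrast == contrast, ]
      sig[r, f, "d10"] <- tk$p_adj[tk$day == 10] < alpha
      sig[r, f, "d35"] <- tk$p_adj[tk$day == 35] < alpha
    }
  }
  per_feature <- data.frame(
    feature = features,
    day10_sig_rate = apply(sig[, , "d10", drop = FALSE], 2, mean,
                           na.rm = TRUE),
    day35_sig_rate = apply(sig[, , "d35", drop = FALSE], 2, mean,
                           na.rm = TRUE))
  rownames(per_feature) <- NULL
  list(per_feature = per_feature, sig = sig)
}
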