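#' Two-way ANOVA with Tukey multiple comparisons for one feature
#'
#' Fixed-effects two-factor ANOVA with interaction on section-level values.
#' Unbalanced designs are handled with Type II sums of squares; the Tukey
#' table compares all genotype groups pairwise within each day
#' (Tukey-Kramer on unequal ns). If any factor cell is empty the
#' interaction is dropped with a warning; a feature that is constant across
#' all sections is returned flagged, with no test.
#'
#' @param ft `feature_table` (or data.frame) with the factor columns and
#'   the feature.
#' @param feature feature column name.
#' @param factors two factor column names, default `c("group", "day")`;
#'   Tukey contrasts are between levels of the first factor within each
#'   level of the second.
#' @return an `anova_result`: `feature`, `table` (term, sumsq, df,
#'   statistic, p_value; includes Residuals), `tukey` (per-day pairwise
#'   contrasts with Tukey-adjusted and unadjusted p-values), `model`,
#'   `flagged`.
#' @export
two_way_anova <- function(ft, feature, factors = c("group", "day")) {
  stopifnot(length(factors) == 2L, feature %in% names(ft),
            all(factors %in% names(ft)))
  fA <- factors[1]; fB <- factors[2]
  df <- data.frame(y = ft[[feature]],
                   A = factor(ft[[fA]]), B = factor(ft[[fB]]))
  names(df) <- c("y", fA, fB)
  df <- df[complete.cases(df), , drop = FALSE]
  if (nlevels(droplevels(df[[fA]])) < 2L ||
      nlevels(droplevels(df[[fB]])) < 2L)
    stop("two_way_anova requires >= 2 levels per factor")
  df[[fA]] <- droplevels(df[[fA]]); df[[fB]] <- droplevels(df[[fB]])
  if (sd(df$y) == 0) {
    return(structure(list(feature = feature, table = NULL, tukey = NULL,
                          model = NULL, flagged = TRUE,
                          reason = "feature constant across sections"),
                     class = "anova_result"))
  }
  cells <- table(df[[fA]], df[[fB]])
  with_int <- all(cells > 0)
  if (!with_int)
    warning("empty factor cells: interaction dropped for ", feature)
  form <- if (with_int)
    stats::as.formula(paste("y ~", fA, "*", fB))
  else stats::as.formula(paste("y ~", fA, "+", fB))
  model <- lm(form, data = df)
  a2 <- car::Anova(model, type = 2)
  tab <- data.frame(term = rownames(a2), sumsq = a2[["Sum Sq"]],
                    df = a2$Df, statistic = a2[["F value"]],
                    p_value = a2[["Pr(>F)"]], stringsAsFactors = FALSE)
  tukey <- tryCatch({
    emm <- emmeans::emmeans(model, stats::as.formula(paste("~", fA, "|", fB)))
    tk <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                          adjust = "tukey"))
    un <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                          adjust = "none"))
    if (nrow(tk) == 0L || length(tk$contrast) == 0L) NULL else {
      out <- data.frame(tk[[fB]], contrast = tk$contrast,
                        estimate = tk$estimate, se = tk$SE, df = tk$df,
                        t_ratio = tk$t.ratio, p_adj = tk$p.value,
                        p_unadj = un$p.value, stringsAsFactors = FALSE)
      names(out)[1] <- fB
      out
    }
  }, error = function(e) NULL)
  structure(list(feature = feature, table = tab, tukey = tukey,
                 model = model, flagged = FALSE),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat("two-way ANOVA:", x$feature, "\n")
  if (x$flagged) cat("  flagged:", x$reason, "\n") else print(x$table)
  invisible(x)
}

#' Clustered heatmap of group x day feature means
#'
#' The clustergram view: per-feature z-scores of the group x day mean
#' matrix, hierarchically clustered on both axes (Euclidean distance,
#' average linkage); orders are deterministic given the table. Features
#' with zero variance across group x day cells are dropped with a message.
#'
#' @param ft `feature_table`.
#' @param features feature columns (default: all numeric feature columns).
#' @param file optional path; if given, a heatmap figure (via
#'   \pkg{pheatmap}) is written there (png or pdf by extension).
#' @param distance,linkage clustering options passed to [stats::dist()] /
#'   [stats::hclust()].
#' @return list with `matrix` (z-scored features x group_day), `row_hclust`,
#'   `col_hclust`, `dropped` (zero-variance features).
#' @export
cluster_heatmap <- function(ft, features = NULL, file = NULL,
                            distance = "euclidean", linkage = "average") {
  keys <- c("line", "group", "day", "section_id")
  if (is.null(features))
    features <- setdiff(names(ft)[vapply(ft, is.numeric, logical(1))],
                        c(keys, "day"))
  cellkey <- interaction(ft$group, ft$day, sep = "_d", drop = TRUE)
  ord <- order(vapply(strsplit(levels(cellkey), "_d"),
                      function(v) as.numeric(v[2]), numeric(1)),
               levels(cellkey))
  M <- sapply(features, function(f)
    tapply(ft[[f]], cellkey, mean, na.rm = TRUE))
  M <- t(M)[, levels(cellkey)[ord], drop = FALSE]
  if (ncol(M) < 2L) stop("cluster_heatmap needs >= 2 group x day cells")
  vr <- apply(M, 1, function(r) sd(r, na.rm = TRUE))
  dropped <- rownames(M)[!is.finite(vr) | vr == 0]
  if (length(dropped))
    message("dropping zero-variance features: ",
            paste(dropped, collapse = ", "))
  M <- M[is.finite(vr) & vr > 0, , drop = FALSE]
  if (nrow(M) == 0L) stop("all features constant; nothing to cluster")
  Z <- t(scale(t(M)))
  row_hc <- stats::hclust(stats::dist(Z, method = distance),
                          method = linkage)
  col_hc <- stats::hclust(stats::dist(t(Z), method = distance),
                          method = linkage)
  if (!is.null(file)) {
    pheatmap::pheatmap(Z, cluster_rows = row_hc, cluster_cols = col_hc,
                       filename = file, silent = TRUE)
  }
  list(matrix = Z, row_hclust = row_hc, col_hclust = col_hc,
       dropped = dropped)
}

#' Group x day summary report of the phenotype features
#'
#' Mean +/- SEM per group x day for each tested feature, with the Tukey
#' within-day significance annotations (the bar-plot layout of the
#' phenotyping readouts: TH/FOXA2 double-positive signal, node count,
#' TH-negative/FOXA2-positive signal).
#'
#' @param ft `feature_table`.
#' @param results named list of `anova_result` objects (may be empty).
#' @return a `phenotype_report`: per feature a `summary` data.frame
#'   (group, day, n, mean, sem) and the `tukey` table with significance
#'   stars.
#' @export
phenotype_report <- function(ft, results) {
  out <- list()
  for (f in names(results)) {
    res <- results[[f]]
    v <- ft[[f]]
    ok <- !is.na(v)
    sm <- aggregate(list(value = v[ok]),
                    by = list(group = ft$group[ok], day = ft$day[ok]),
                    FUN = function(x) c(n = length(x), mean = mean(x),
                                        sem = sd(x) / sqrt(length(x))))
    summary <- data.frame(group = sm$group, day = sm$day,
                          n = sm$value[, "n"], mean = sm$value[, "mean"],
                          sem = sm$value[, "sem"])
    summary <- summary[order(summary$day, summary$group), ]
    rownames(summary) <- NULL
    tukey <- if (!res$flagged && !is.null(res$tukey)) {
      tk <- res$tukey
      tk$stars <- stars_for(tk$p_adj)
      tk
    } else NULL
    out[[f]] <- list(summary = summary, tukey = tukey,
                     flagged = res$flagged)
  }
  structure(out, class = "phenotype_report")
}

stars_for <- function(p) {
  ifelse(p < 1e-4, "****", ifelse(p < 1e-3, "***",
    ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns"))))
}

#' @export
print.phenotype_report <- function(x, ...) {
  if (length(x) == 0L) { cat("phenotype_report: empty\n"); return(invisible(x)) }
  for (f in names(x)) {
    cat("==", f, if (x[[f]]$flagged) "(flagged)", "\n")
    print(x[[f]]$summary, digits = 3)
    if (!is.null(x[[f]]$tukey)) print(x[[f]]$tukey, digits = 3)
  }
  invisible(x)
}
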