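#!/usr/bin/env Rscript

# Run the full image-analysis pipeline over the simulated cohort written by
# 01_simulate_cohort.R: nuclei + marker segmentation, skeleton topology,
# per-cell scoring, feature assembly, two-way ANOVA with Tukey comparisons,
# and the clustered feature heatmap. All tables land in results/phenotype.

library(organoidHCA)

cohort_dir <- "results/cohort"
outdir <- "results/phenotype"
if (!file.exists(file.path(cohort_dir, "manifest.csv")))
  stop("run analysis/01_simulate_cohort.R first")

manifest <- read.csv(file.path(cohort_dir, "manifest.csv"))
roles <- readLines(file.path(cohort_dir, "channels.txt"))

cfg <- pipeline_config()
res <- run_pipeline(manifest, cfg, channel_roles = roles, outdir = outdir)

cat("analyzed", sum(res$runlog$status == "ok"), "of", nrow(manifest),
    "sections\n")
hm <- cluster_heatmap(res$features, file = file.path(outdir, "heatmap.png"))
cat("heatmap over", nrow(hm$matrix), "features x", ncol(hm$matrix),
    "group-day cells; column order:",
    paste(colnames(hm$matrix)[hm$col_hclust$order], collapse = " "), "\n")

print(res$report)
cat("outputs in", outdir, "\n")
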