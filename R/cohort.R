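#' Define one genotype x day group of a synthetic cohort
#'
#' @param group genotype label (e.g. "H", "P", "H-G2019S", "P-GC").
#' @param day differentiation day (e.g. 10, 35, 70).
#' @param n_sections number of organoid sections to simulate.
#' @param deltas named list of parameter overrides applied on top of the
#'   base [synth_params()]. Besides any `synth_params` field, two shortcuts
#'   are understood: `marker_fractions` (named list of per-marker positive
#'   fractions) and `bifurcation_prob`.
#' @param lines cell-line labels cycled over sections (default two lines
#'   per group).
#' @return a `cohort_group` list.
#' @export
cohort_group <- function(group, day, n_sections, deltas = list(),
                         lines = paste0(group, ".", 1:2)) {
  stopifnot(is.character(group), length(group) == 1L, n_sections >= 0)
  structure(list(group = group, day = as.integer(day),
                 n_sections = as.integer(n_sections),
                 deltas = deltas, lines = lines),
            class = "cohort_group")
}

apply_deltas <- function(base, deltas) {
  if (length(deltas) == 0L) return(base)
  mf <- deltas$marker_fractions
  bp <- deltas$bifurcation_prob
  deltas$marker_fractions <- NULL
  deltas$bifurcation_prob <- NULL
  p <- merge_params(base, deltas)
  if (!is.null(mf)) {
    for (nm in names(mf)) {
      hit <- FALSE
      for (k in seq_along(p$marker_profiles)) {
        if (p$marker_profiles[[k]]$name == tolower(nm)) {
          p$marker_profiles[[k]]$positive_fraction <- mf[[nm]]
          hit <- TRUE
        }
      }
      if (!hit) stop("marker_fractions delta for unknown marker: ", nm)
    }
  }
  if (!is.null(bp)) p$neurite_params$bifurcation_prob <- bp
  class(p) <- "synth_params"
  validate_synth_params(p)
  p
}

#' Generate a synthetic organoid cohort
#'
#' Simulates one section image (and/or ground truth) per manifest row, with
#' per-group parameter deltas on top of a base parameter set — e.g. reduced
#' TH fraction and bifurcation probability, and an elevated TH-/FOXA2+
#' fraction, in the mutation-carrying groups at later differentiation days.
#' Per-section seeds are derived deterministically from the base seed, so
#' the whole cohort is reproducible from `base` plus `group_specs`.
#'
#' @param group_specs list of [cohort_group()] definitions.
#' @param base base [synth_params()].
#' @param outdir if non-`NULL`, images are written as multi-page TIFF,
#'   ground truth as per-cell CSV plus per-image JSON totals, and the
#'   manifest as `manifest.csv` in this directory.
#' @param render render pixels (`TRUE`) or produce ground truth only.
#' @param keep_images keep rendered images in memory in the returned list
#'   (default `TRUE` when `outdir` is `NULL`).
#' @return list with `manifest` (data.frame: path, line, group, day,
#'   section_id), `images` (named list of [image_stack()] or `NULL`) and
#'   `truths` (named list of ground truths).
#' @export
generate_cohort <- function(group_specs, base = synth_params(),
                            outdir = NULL, render = TRUE,
                            keep_images = is.null(outdir)) {
  validate_synth_params(base)
  rows <- list(); images <- list(); truths <- list()
  idx <- 0L
  for (gs in group_specs) {
    p_group <- apply_deltas(base, gs$deltas)
    for (s in seq_len(gs$n_sections)) {
      idx <- idx + 1L
      sid <- sprintf("%s_d%02d_s%03d", gs$group, gs$day, s)
      p_sec <- p_group
      p_sec$seed <- as.integer((base$seed + 100003 * idx) %% 2147483647)
      sec <- generate_section(p_sec, render = render)
      path <- NA_character_
      if (!is.null(outdir) && render) {
        path <- file.path(outdir, paste0(sid, ".tif"))
        write_stack(sec$image, path)
      }
      if (!is.null(outdir)) {
        write.csv(sec$truth$cells,
                  file.path(outdir, paste0(sid, "_truth_cells.csv")),
                  row.names = FALSE)
        jsonlite::write_json(sec$truth$totals,
                             file.path(outdir, paste0(sid, "_truth.json")),
                             auto_unbox = TRUE, digits = NA)
      }
      rows[[idx]] <- data.frame(
        path = path, line = gs$lines[(s - 1L) %% length(gs$lines) + 1L],
        group = gs$group, day = gs$day, section_id = sid,
        stringsAsFactors = FALSE)
      if (render && keep_images) images[[sid]] <- sec$image
      truths[[sid]] <- sec$truth
    }
  }
  manifest <- if (idx) do.call(rbind, rows) else
    data.frame(path = character(0), line = character(0),
               group = character(0), day = integer(0),
               section_id = character(0))
  if (anyDuplicated(manifest$section_id))
    stop("duplicate section ids in cohort design")
  if (!is.null(outdir))
    write.csv(manifest, file.path(outdir, "manifest.csv"), row.names = FALSE)
  list(manifest = manifest,
       images = if (length(images)) images else NULL,
       truths = truths)
}

#' Ground-truth feature table of a synthetic cohort
#'
#' Per-section feature rows computed from the generator's ground truth
#' (no image analysis); used for fast statistical calibration (null
#' distribution, power) of the phenotyping ANOVA.
#'
#' @param cohort result of [generate_cohort()].
#' @return data.frame keyed by (line, group, day, section_id).
#' @export
truth_features <- function(cohort) {
  man <- cohort$manifest
  rows <- lapply(seq_len(nrow(man)), function(i) {
    tt <- cohort$truths[[man$section_id[i]]]$totals
    data.frame(line = man$line[i], group = man$group[i], day = man$day[i],
               section_id = man$section_id[i],
               n_cells = tt$n_viable,
               pyknotic_fraction = tt$n_pyknotic / max(1L, tt$n_cells),
               th_cell_fraction = tt$th_fraction %||% NA_real_,
               foxa2_cell_fraction = tt$foxa2_fraction %||% NA_real_,
               th_foxa2_cell_fraction = tt$th_foxa2_fraction %||% NA_real_,
               th_neg_foxa2_cell_fraction =
                 tt$th_neg_foxa2_fraction %||% NA_real_,
               n_nodes = tt$n_nodes, n_links = tt$n_links,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Paper-motivated cohort design
#'
#' Convenience constructor for the genotype x day factor design used in the
#' phenotyping study: groups H, P, H-G2019S, P-GC at differentiation days
#' 10/35/70, with disease effects (reduced TH fraction, reduced bifurcation
#' probability, elevated FOXA2+/TH- progenitor fraction) injected into the
#' mutation-carrying groups (P, H-G2019S) at days 35 and 70 only.
#'
#' @param n_sections sections per group x day cell.
#' @param groups genotype labels.
#' @param days differentiation days.
#' @param affected groups receiving the disease deltas.
#' @param effect list with the affected-group parameter values
#'   `th_fraction`, `foxa2_fraction`, `bifurcation_prob` applied at
#'   `days > 10`; `NULL` entries leave the base value.
#' @param null_cohort if `TRUE`, no deltas anywhere (for type-I-error
#'   calibration).
#' @return list of [cohort_group()] specs.
#' @export
pd_cohort_design <- function(n_sections = 20,
                             groups = c("H", "P", "H-G2019S", "P-GC"),
                             days = c(10, 35, 70),
                             affected = c("P", "H-G2019S"),
                             effect = list(th_fraction = 0.35,
                                           foxa2_fraction = 0.75,
                                           bifurcation_prob = 0.25),
                             null_cohort = FALSE) {
  specs <- list()
  for (g in groups) for (d in days) {
    deltas <- list()
    if (!null_cohort && g %in% affected && d > 10) {
      mf <- list()
      if (!is.null(effect$th_fraction)) mf$th <- effect$th_fraction
      if (!is.null(effect$foxa2_fraction)) mf$foxa2 <- effect$foxa2_fraction
      if (length(mf)) deltas$marker_fractions <- mf
      if (!is.null(effect$bifurcation_prob))
        deltas$bifurcation_prob <- effect$bifurcation_prob
    }
    specs[[length(specs) + 1L]] <-
      cohort_group(g, d, n_sections, deltas = deltas)
  }
  specs
}
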