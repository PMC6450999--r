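#' Extract the full feature set of one image
#'
#' Runs segmentation, marker masks, skeleton topology and per-cell scoring
#' on one [image_stack()] and returns the per-image feature row plus a log
#' of applied thresholds and quality flags. Cell fractions of low-quality
#' images (fewer retained nuclei than `scoring$min_cells`) are reported as
#' `NA` but pixel fractions are kept.
#'
#' @param img [image_stack()].
#' @param cfg [pipeline_config()].
#' @return list with `features` (named list of numerics) and `log`.
#' @export
image_features <- function(img, cfg = pipeline_config()) {
  seg <- segment_nuclei(img, cfg$seg, mode = cfg$mode)
  seg <- label_nuclei(seg, cfg$seg)
  markers <- setdiff(names(img$channels), "hoechst")
  masks <- lapply(markers, function(m)
    marker_mask(img, m, cfg$seg, nuclei = seg, mode = cfg$mode))
  names(masks) <- markers

  zones <- perinuclear_zones(seg, cfg$scoring$ring_width)
  calls <- call_cells(seg, zones, masks,
                      min_fraction = cfg$scoring$min_fraction,
                      nuclear_markers = cfg$scoring$nuclear_markers,
                      min_cells = cfg$scoring$min_cells)
  pxf <- pixel_fractions(masks, seg)

  feat <- list(n_cells = calls$n_cells)
  pyk_px <- sum(seg$pyknotic_mask); nuc_px <- sum(seg$nuclei_mask)
  feat$pyknotic_fraction <-
    if (pyk_px + nuc_px > 0) pyk_px / (pyk_px + nuc_px) else NA_real_
  for (m in markers) {
    feat[[paste0(m, "_px_fraction")]] <- pxf$fractions[[m]]
    feat[[paste0(m, "_cell_fraction")]] <-
      if (calls$low_quality) NA_real_ else calls$fractions[[paste0(m, "_pos")]]
  }
  if (all(c("th", "foxa2") %in% markers)) {
    feat$th_foxa2_px_fraction <- pxf$fractions$th_foxa2
    feat$foxa2_not_th_px_fraction <- pxf$fractions$foxa2_not_th
    feat$th_foxa2_cell_fraction <-
      if (calls$low_quality) NA_real_ else calls$fractions$th_foxa2
    feat$th_neg_foxa2_cell_fraction <-
      if (calls$low_quality) NA_real_ else calls$fractions$th_neg_foxa2
  }
  if ("th" %in% markers) {
    sk <- count_nodes_links(skeletonize(masks$th,
                                        prune = cfg$skeleton$prune))
    feat$n_nodes <- sk$n_nodes
    feat$n_links <- sk$n_links
    feat$links_per_node <-
      if (sk$n_nodes > 0) sk$n_links / sk$n_nodes else NA_real_
  }
  list(features = feat,
       log = list(nuclei_threshold = seg$thresholds$nuclei,
                  pyknotic_threshold = seg$thresholds$pyknotic,
                  marker_thresholds =
                    vapply(masks, `[[`, numeric(1), "threshold"),
                  n_removed_oversize = length(seg$removed_oversize_ids),
                  low_quality = calls$low_quality,
                  px_flagged = pxf$flagged))
}

#' Assemble the per-section feature table
#'
#' One row per section; when a section was imaged as several fields
#' (repeated `section_id` in the manifest), field features are averaged.
#' Manifest rows without per-image output are dropped and logged as
#' exclusions.
#'
#' @param manifest data.frame with columns path, line, group, day,
#'   section_id.
#' @param per_image named list (by manifest row name `section_id:field` or
#'   `section_id`) of [image_features()] results or plain feature lists.
#' @return a `feature_table` data.frame; excluded sections in
#'   `attr(, "exclusions")`.
#' @export
assemble_features <- function(manifest, per_image) {
  need <- c("line", "group", "day", "section_id")
  if (!all(need %in% names(manifest)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  keys <- unique(manifest[need])
  if (is.null(names(per_image))) names(per_image) <- character(length(per_image))
  rows <- list(); excl <- list()
  for (i in seq_len(nrow(keys))) {
    sid <- keys$section_id[i]
    fields <- per_image[names(per_image) == sid |
                        startsWith(names(per_image), paste0(sid, ":"))]
    if (length(fields) == 0L) {
      excl[[length(excl) + 1L]] <-
        data.frame(section_id = sid, reason = "no per-image output")
      next
    }
    mats <- lapply(fields, function(f)
      unlist(if (!is.null(f$features)) f$features else f))
    cn <- names(mats[[1]])
    if (!all(vapply(mats, function(v) identical(names(v), cn), logical(1))))
      stop("inconsistent feature names across fields of section ", sid)
    agg <- colMeans(do.call(rbind, mats), na.rm = TRUE)
    agg[is.nan(agg)] <- NA_real_
    rows[[length(rows) + 1L]] <-
      cbind(keys[i, , drop = FALSE], as.data.frame(as.list(agg)))
  }
  if (length(rows) == 0L)
    stop("no sections with per-image outputs")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("feature_table", "data.frame")
  attr(out, "exclusions") <- if (length(excl)) do.call(rbind, excl) else NULL
  out
}
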