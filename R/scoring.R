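#' Perinuclear zones of retained nuclei
#'
#' For every retained watershed label, the perinuclear zone is the ring of
#' background pixels within `ring_width` growth steps of the nucleus
#' (iterated 8-neighbor dilation). Where rings of adjacent nuclei would
#' overlap, each pixel is assigned to the nucleus reached first (the
#' nearer one in the dilation metric); on a tie the lower label id wins.
#' Zones never include nucleus pixels.
#'
#' @param seg labelled `nuclei_segmentation` (or an integer label matrix).
#' @param ring_width ring width in pixels (>= 1).
#' @return a `perinuclear_zones` list: `zone_labels` (integer matrix, 0 =
#'   no zone), `ring_width`, `labels` (retained ids).
#' @export
perinuclear_zones <- function(seg, ring_width = 3) {
  if (ring_width < 1) stop("ring_width must be >= 1")
  labels <- if (inherits(seg, "nuclei_segmentation")) seg$labels else seg
  stopifnot(is.matrix(labels))
  nucleus <- labels > 0L
  grown <- grow_labels_cpp(labels, as.integer(ring_width))
  zone <- grown
  zone[nucleus] <- 0L
  ids <- sort(unique(as.vector(labels)))
  structure(list(zone_labels = zone, ring_width = ring_width,
                 labels = ids[ids > 0L]),
            class = "perinuclear_zones")
}

#' Call per-cell marker positivity
#'
#' A cell is positive for a marker iff the marker mask covers at least
#' `min_fraction` (default 1%) of the cell's scoring region. Cytoplasmic
#' markers (TH) are scored on the perinuclear zone; nuclear markers
#' (default FOXA2, SOX2) on the nucleus pixel set itself, consistent with
#' their masks being restricted to nuclei. Per-image counts and fractions
#' of retained cells are derived, including the TH/FOXA2 double-positive
#' and TH-negative/FOXA2-positive readouts.
#'
#' @param seg labelled `nuclei_segmentation`.
#' @param zones [perinuclear_zones()] of the same image.
#' @param masks list of `marker_mask` objects (named or not).
#' @param min_fraction positivity rule threshold (inclusive).
#' @param nuclear_markers markers scored on the nucleus pixel set.
#' @param min_cells sections with fewer retained cells are flagged
#'   low-quality (fractions still computed, flag carried downstream).
#' @return a `cell_calls` list: `calls` (long data.frame: label, marker,
#'   fraction, positive), `counts`, `fractions`, `n_cells`, `low_quality`.
#' @export
call_cells <- function(seg, zones, masks, min_fraction = 0.01,
                       nuclear_markers = c("foxa2", "sox2"),
                       min_cells = 10) {
  ids <- retained_labels(seg)
  if (length(masks) && inherits(masks, "marker_mask")) masks <- list(masks)
  for (mm in masks)
    if (!all(dim(mm$mask) == dim(seg$labels)))
      stop("marker mask shape does not match segmentation")
  kmax <- if (length(ids)) max(ids) else 0L
  calls <- list()
  pos_mat <- matrix(FALSE, nrow = length(ids), ncol = 0)
  for (mm in masks) {
    domain <- if (mm$marker %in% nuclear_markers) seg$labels
              else zones$zone_labels
    area <- tabulate(domain[domain > 0L], nbins = kmax)
    inside <- domain[mm$mask & domain > 0L]
    overlap <- tabulate(inside, nbins = kmax)
    frac <- ifelse(area > 0, overlap / area, 0)[ids]
    positive <- frac >= min_fraction
    calls[[mm$marker]] <- data.frame(label = ids, marker = mm$marker,
                                     fraction = frac, positive = positive,
                                     stringsAsFactors = FALSE)
    pos_mat <- cbind(pos_mat, positive)
    colnames(pos_mat)[ncol(pos_mat)] <- mm$marker
  }
  n <- length(ids)
  counts <- list(n_cells = n)
  for (m in colnames(pos_mat)) counts[[paste0(m, "_pos")]] <-
    sum(pos_mat[, m])
  if (all(c("th", "foxa2") %in% colnames(pos_mat))) {
    counts$th_foxa2 <- sum(pos_mat[, "th"] & pos_mat[, "foxa2"])
    counts$th_neg_foxa2 <- sum(!pos_mat[, "th"] & pos_mat[, "foxa2"])
  }
  fractions <- lapply(counts[setdiff(names(counts), "n_cells")],
                      function(k) if (n > 0) k / n else NA_real_)
  structure(list(calls = do.call(rbind, calls), counts = counts,
                 fractions = fractions, n_cells = n,
                 low_quality = n < min_cells),
            class = "cell_calls")
}

#' Pixel-fraction marker quantification
#'
#' Mode (i) of the expression readouts: positive marker pixels normalized
#' by the pixel count of the Hoechst (nuclei) mask, plus the TH-and-FOXA2
#' overlap and FOXA2-without-TH fractions under the same normalization.
#'
#' @param masks list of `marker_mask` objects.
#' @param nuclei `nuclei_segmentation`.
#' @return a `pixel_fractions` list: `fractions` (named, per marker plus
#'   `th_foxa2` and `foxa2_not_th`), `denominator`, `flagged` (`TRUE` when
#'   the nuclei mask is empty and the fractions are undefined).
#' @export
pixel_fractions <- function(masks, nuclei) {
  denom <- sum(nuclei$nuclei_mask)
  if (length(masks) && inherits(masks, "marker_mask")) masks <- list(masks)
  named <- setNames(masks, vapply(masks, `[[`, "", "marker"))
  out <- list()
  if (denom == 0) {
    for (m in names(named)) out[[m]] <- NA_real_
    if (all(c("th", "foxa2") %in% names(named)))
      out[c("th_foxa2", "foxa2_not_th")] <- NA_real_
    return(structure(list(fractions = out, denominator = 0L,
                          flagged = TRUE), class = "pixel_fractions"))
  }
  for (m in names(named)) out[[m]] <- sum(named[[m]]$mask) / denom
  if (all(c("th", "foxa2") %in% names(named))) {
    out$th_foxa2 <- sum(named$th$mask & named$foxa2$mask) / denom
    out$foxa2_not_th <- sum(named$foxa2$mask & !named$th$mask) / denom
  }
  structure(list(fractions = out, denominator = denom, flagged = FALSE),
            class = "pixel_fractions")
}
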