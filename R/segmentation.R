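#' Segment nuclei and the pyknotic population from the Hoechst channel
#'
#' The Hoechst channel is smoothed with a Gaussian filter and thresholded to
#' give the nuclei mask. Pixels above the pyknotic threshold (on the same
#' smoothed channel) identify condensed, hyper-intense nuclei of dying
#' cells; their mask is dilated by `pyknotic_dilate` pixels and subtracted
#' from the nuclei mask, so the two returned masks are disjoint.
#'
#' @param img [image_stack()] (a stack is reduced per `mode`).
#' @param p [seg_params()].
#' @param mode "mip" (maximum-intensity projection) or "plane" with
#'   `plane` index, for 3D inputs.
#' @param plane z-plane when `mode = "plane"`.
#' @return a `nuclei_segmentation` list: `nuclei_mask`, `pyknotic_mask`
#'   (both logical matrices), empty `labels`, and the applied thresholds.
#' @export
segment_nuclei <- function(img, p = seg_params(), mode = c("mip", "plane"),
                           plane = 1L) {
  mode <- match.arg(mode)
  ch <- get_channel(img, "hoechst", mode, plane)
  if (any(!is.finite(ch))) stop("non-finite pixels in hoechst channel")
  empty <- matrix(FALSE, nrow(ch), ncol(ch))
  smooth <- if (p$gaussian_sigma > 0)
    gaussian_blur_cpp(ch, p$gaussian_sigma) else ch
  if (diff(range(smooth)) == 0) {
    return(new_nuclei_segmentation(empty, empty, thresholds =
      list(nuclei = NA_real_, pyknotic = NA_real_)))
  }
  thr <- resolve_threshold(as.vector(smooth),
                           channel_threshold(p, "hoechst"))
  nuclei0 <- smooth > thr
  pthr <- if ((p$pyknotic_threshold$method %||% "fixed") == "quantile")
    resolve_threshold(smooth[nuclei0], p$pyknotic_threshold)
  else resolve_threshold(as.vector(smooth), p$pyknotic_threshold)
  pyk_raw <- smooth > pthr & nuclei0
  pyk <- if (p$pyknotic_dilate > 0 && any(pyk_raw))
    as.matrix(EBImage::dilate(EBImage::Image(pyk_raw + 0),
      EBImage::makeBrush(2 * p$pyknotic_dilate + 1, "disc"))) > 0
  else pyk_raw
  pyk <- pyk & nuclei0
  new_nuclei_segmentation(nuclei0 & !pyk, pyk,
                          thresholds = list(nuclei = thr, pyknotic = pthr))
}

#' Construct a nuclei segmentation object
#'
#' Builds the container returned by [segment_nuclei()] from user-supplied
#' masks, e.g. to run [label_nuclei()] or the scoring stage on masks made
#' elsewhere.
#'
#' @param nuclei_mask,pyknotic_mask logical matrices (disjoint).
#' @param labels optional integer label matrix.
#' @param removed_oversize_ids,removed_undersize_ids label ids removed by
#'   the size rules.
#' @param thresholds named list of the thresholds applied.
#' @return a `nuclei_segmentation` object.
#' @export
new_nuclei_segmentation <- function(nuclei_mask, pyknotic_mask,
                                    labels = NULL,
                                    removed_oversize_ids = integer(0),
                                    removed_undersize_ids = integer(0),
                                    thresholds = list()) {
  structure(list(nuclei_mask = nuclei_mask, pyknotic_mask = pyknotic_mask,
                 labels = labels,
                 removed_oversize_ids = removed_oversize_ids,
                 removed_undersize_ids = removed_undersize_ids,
                 thresholds = thresholds),
            class = "nuclei_segmentation")
}

#' @export
print.nuclei_segmentation <- function(x, ...) {
  cat("nuclei_segmentation:", sum(x$nuclei_mask), "nuclei px,",
      sum(x$pyknotic_mask), "pyknotic px,",
      if (is.null(x$labels)) "unlabelled"
      else paste(length(retained_labels(x)), "labels"), "\n")
  invisible(x)
}

#' Separate single nuclei by watershed and apply the size exclusion
#'
#' Seeds are the h-maxima of the Euclidean distance transform
#' (suppression depth `watershed_h`); basins partition the nuclei mask into
#' single nuclei. Labels with strictly more than `max_nucleus_size` pixels
#' are removed (clumps the watershed failed to separate), and labels below
#' `min_nucleus_size` are dropped as debris; both removals are recorded.
#'
#' @param seg `nuclei_segmentation` from [segment_nuclei()].
#' @param p [seg_params()].
#' @return the segmentation with `labels` filled (integer matrix, 0 =
#'   background; removed labels zeroed out but their ids recorded).
#' @export
label_nuclei <- function(seg, p = seg_params()) {
  mask <- seg$nuclei_mask
  if (!any(mask)) {
    seg$labels <- matrix(0L, nrow(mask), ncol(mask))
    return(seg)
  }
  dm <- EBImage::distmap(EBImage::Image(mask + 0))
  ws <- EBImage::watershed(dm, tolerance = p$watershed_h, ext = 1)
  labels <- matrix(as.integer(ws), nrow(mask))
  k <- max(labels)
  sizes <- tabulate(labels, nbins = k)
  over <- which(sizes > p$max_nucleus_size)
  under <- which(sizes > 0 & sizes < p$min_nucleus_size)
  labels[labels %in% c(over, under)] <- 0L
  seg$labels <- labels
  seg$removed_oversize_ids <- over
  seg$removed_undersize_ids <- under
  seg
}

#' Retained label ids of a labelled segmentation
#' @param seg `nuclei_segmentation` with labels.
#' @return integer vector of retained label ids.
#' @export
retained_labels <- function(seg) {
  stopifnot(!is.null(seg$labels))
  ids <- sort(unique(as.vector(seg$labels)))
  ids[ids > 0L]
}

#' Build a marker mask
#'
#' Median-filters the marker channel, thresholds it, and removes connected
#' components with strictly fewer than `min_component_size` pixels (not
#' applied to TH unless `th_small_removal` is set, since the removal step is
#' defined for the nuclear markers). When a nuclei segmentation is supplied
#' and the marker is nuclear (SOX2/FOXA2), the mask is restricted to the
#' nuclei mask.
#'
#' @param img [image_stack()].
#' @param marker channel role name.
#' @param p [seg_params()].
#' @param nuclei optional `nuclei_segmentation` for the restriction.
#' @param mode,plane as in [segment_nuclei()].
#' @return a `marker_mask` list: `marker`, `mask` (logical),
#'   `min_component_size`, `restricted_to_nuclei`, `threshold`.
#' @export
marker_mask <- function(img, marker, p = seg_params(), nuclei = NULL,
                        mode = c("mip", "plane"), plane = 1L) {
  mode <- match.arg(mode)
  marker <- tolower(marker)
  if (!marker %in% names(img$channels))
    stop("unknown marker role: ", marker)
  ch <- get_channel(img, marker, mode, plane)
  med <- if (p$median_radius > 0) median_filter(ch, p$median_radius) else ch
  if (diff(range(med)) == 0) {
    mask <- matrix(FALSE, nrow(ch), ncol(ch))
    thr <- NA_real_
  } else {
    thr <- resolve_threshold(as.vector(med), channel_threshold(p, marker))
    mask <- med > thr
    if (marker != "th" || isTRUE(p$th_small_removal))
      mask <- remove_small_components(mask, p$min_component_size,
                                      p$connectivity)
  }
  restricted <- FALSE
  if (!is.null(nuclei) && marker %in% c("sox2", "foxa2")) {
    mask <- mask & nuclei$nuclei_mask
    restricted <- TRUE
  }
  structure(list(marker = marker, mask = mask,
                 min_component_size = p$min_component_size,
                 restricted_to_nuclei = restricted, threshold = thr),
            class = "marker_mask")
}

channel_threshold <- function(p, channel) {
  p$thresholds[[channel]] %||% p$thresholds$default %||%
    list(method = "otsu")
}

# extract a 2D matrix for one channel role, reducing stacks per mode
get_channel <- function(img, role, mode = "mip", plane = 1L) {
  stopifnot(inherits(img, "image_stack"))
  ch <- img$channels[[tolower(role)]]
  if (is.null(ch)) stop("channel role not present: ", role)
  if (length(dim(ch)) == 3L) {
    if (mode == "mip") {
      out <- ch[, , 1]
      if (dim(ch)[3] > 1)
        for (z in 2:dim(ch)[3]) out <- pmax(out, ch[, , z])
      out
    } else ch[, , plane]
  } else ch
}
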