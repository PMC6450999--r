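#' Label connected components of a binary mask
#'
#' Deterministic flood-fill labelling (labels follow column-major first-pixel
#' order) with selectable pixel connectivity.
#'
#' @param mask logical or 0/1 integer matrix.
#' @param connectivity 4 or 8 (default 8, the convention used throughout the
#'   pipeline).
#' @return integer matrix of component labels, 0 = background.
#' @export
label_components <- function(mask, connectivity = 8) {
  m <- as_binary_matrix(mask)
  label_cc_cpp(m, as.integer(connectivity))
}

#' Remove small connected components from a binary mask
#'
#' Drops every connected component with strictly fewer than `min_size`
#' pixels (the `bwareaopen` convention: a component of exactly `min_size`
#' pixels is kept).
#'
#' @param mask logical or 0/1 matrix.
#' @param min_size minimum pixel count a component must have to be kept.
#' @param connectivity 4 or 8.
#' @return logical matrix.
#' @export
remove_small_components <- function(mask, min_size, connectivity = 8) {
  m <- as_binary_matrix(mask)
  if (min_size <= 1 || !any(m == 1L)) return(m == 1L)
  lab <- label_cc_cpp(m, as.integer(connectivity))
  k <- max(lab)
  if (k == 0L) return(lab > 0L)
  sizes <- tabulate(lab, nbins = k)
  keep <- which(sizes >= min_size)
  matrix(lab %in% keep, nrow = nrow(lab))
}

#' Median filter with a square window
#'
#' Box median with window `(2 * radius + 1)^2` and replicated edges; the
#' default `radius = 1` is the 3x3 filter applied to marker channels before
#' thresholding.
#'
#' @param img numeric matrix.
#' @param radius half-width of the square window in pixels.
#' @return numeric matrix of the same shape.
#' @export
median_filter <- function(img, radius = 1) {
  stopifnot(is.matrix(img))
  median_box_cpp(img, as.integer(radius))
}

# coerce logical/numeric matrix to 0/1 integer matrix
as_binary_matrix <- function(mask) {
  if (!is.matrix(mask)) stop("mask must be a matrix")
  m <- matrix(as.integer(mask != 0), nrow = nrow(mask))
  m
}

# resolve a threshold spec against a vector of intensities.
# spec: list(method = "otsu"|"fixed"|"quantile", value =, q =)
resolve_threshold <- function(values, spec) {
  method <- spec$method %||% "otsu"
  switch(method,
    otsu = otsu_threshold(values),
    fixed = {
      if (is.null(spec$value)) stop("fixed threshold requires 'value'")
      spec$value
    },
    quantile = {
      if (is.null(spec$q)) stop("quantile threshold requires 'q'")
      as.numeric(quantile(values, spec$q, names = FALSE))
    },
    stop("unknown threshold method: ", method)
  )
}

# Otsu on a numeric vector; between-class-variance maximizing cut on a
# 256-bin histogram over the value range.
otsu_threshold <- function(values, levels = 256L) {
  v <- values[is.finite(values)]
  if (length(v) == 0L || diff(range(v)) == 0) return(Inf)
  otsu_cpp(v, min(v), max(v), as.integer(levels))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# quantize intensities to the 16-bit grid used by TIFF storage so that
# in-memory and written/re-read images are bit-identical
quantize16 <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  round(x * 65535) / 65535
}

# deep merge for nested parameter lists (modifyList, recursing into lists)
merge_params <- function(base, delta) {
  if (is.null(delta)) return(base)
  modifyList(base, delta)
}
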