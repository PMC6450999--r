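#' @title Synthetic organoid sections with exact ground truth
#' @description
#' [generate_section()] draws one multichannel immunofluorescence field of a
#' midbrain-organoid section: elliptical Hoechst nuclei (a configurable
#' fraction condensed/pyknotic, drawn smaller and brighter by a separable
#' intensity gain), a nuclear marker channel per "nuclear" profile, and a
#' cytoplasm+neurite channel per "cytoplasmic+neurite" profile in which each
#' positive cell carries a soma disk and a recursively bifurcating neurite
#' tree. The drawn topology (bifurcation count, segment count) and every
#' per-cell positivity flag are returned as exact ground truth. All
#' randomness is a pure function of the parameter set, including its seed.
#' @name synthetic_sections
NULL

# jittered-grid placement guaranteeing centre distance >= 2*rmax,
# with an error if the requested count cannot be packed
place_cells <- function(shape_yx, n, rmax, gap) {
  ny <- shape_yx[1]; nx <- shape_yx[2]
  s <- 2 * rmax + gap
  margin <- rmax + 1
  ky <- max(0L, floor((ny - 2 * margin) / s))
  kx <- max(0L, floor((nx - 2 * margin) / s))
  if (n > ky * kx)
    stop("infeasible packing: cannot place ", n, " cells of radius <= ",
         rmax, " in a ", ny, "x", nx, " image", call. = FALSE)
  if (n == 0L) return(cbind(y = numeric(0), x = numeric(0)))
  cells <- sample.int(ky * kx, n)
  gy <- ((cells - 1L) %% ky) + 1L
  gx <- ((cells - 1L) %/% ky) + 1L
  jit <- gap / 4
  y <- margin + (gy - 0.5) * s + runif(n, -jit, jit)
  x <- margin + (gx - 0.5) * s + runif(n, -jit, jit)
  cbind(y = y, x = x)
}

# pixel set (linear indices into an ny x nx matrix) of a filled ellipse
ellipse_pixels <- function(cy, cx, a, b, theta, ny, nx) {
  r <- ceiling(a) + 1L
  ys <- max(1L, floor(cy - r)):min(ny, ceiling(cy + r))
  xs <- max(1L, floor(cx - r)):min(nx, ceiling(cx + r))
  dy <- outer(ys - cy, rep(1, length(xs)))
  dx <- outer(rep(1, length(ys)), xs - cx)
  u <- (dy * cos(theta) + dx * sin(theta)) / a
  v <- (-dy * sin(theta) + dx * cos(theta)) / b
  keep <- (u * u + v * v) <= 1
  yy <- outer(ys, rep(1L, length(xs)))[keep]
  xx <- outer(rep(1L, length(ys)), xs)[keep]
  as.integer(yy + (xx - 1L) * ny)
}

# rasterize a straight segment as a single-pixel 8-connected chain
# (Bresenham on the rounded endpoints: one pixel per major-axis step)
raster_segment <- function(y0, x0, y1, x1) {
  y0 <- round(y0); x0 <- round(x0); y1 <- round(y1); x1 <- round(x1)
  dy <- y1 - y0; dx <- x1 - x0
  n <- max(abs(dy), abs(dx))
  if (n == 0) return(cbind(y0, x0))
  t <- seq_len(n + 1L) - 1L
  cbind(round(y0 + t * dy / n), round(x0 + t * dx / n))
}

# recursively bifurcating neurite tree; returns pixel coordinates (width 1)
# and the drawn topology
draw_tree <- function(y0, x0, angle0, np) {
  n_nodes <- 0L; n_links <- 0L
  pts <- vector("list", 64L); npts <- 0L
  queue <- list(list(y = y0, x = x0, a = angle0, d = 0L))
  while (length(queue)) {
    seg <- queue[[1]]; queue <- queue[-1]
    len <- runif(1, np$branch_length_range[1], np$branch_length_range[2])
    y1 <- seg$y + len * sin(seg$a); x1 <- seg$x + len * cos(seg$a)
    npts <- npts + 1L
    if (npts > length(pts)) pts <- c(pts, vector("list", length(pts)))
    pts[[npts]] <- raster_segment(seg$y, seg$x, y1, x1)
    n_links <- n_links + 1L
    if (seg$d < np$max_depth && runif(1) < np$bifurcation_prob) {
      n_nodes <- n_nodes + 1L
      spread <- runif(1, 25, 55) * pi / 180
      for (s in c(-1, 1))
        queue[[length(queue) + 1L]] <-
          list(y = y1, x = x1, a = seg$a + s * spread, d = seg$d + 1L)
    }
  }
  list(coords = do.call(rbind, pts[seq_len(npts)]),
       n_nodes = n_nodes, n_links = n_links)
}

# thicken width-1 pixel coordinates to the requested drawn width
thicken <- function(coords, width) {
  if (width <= 1 || is.null(coords)) return(coords)
  offs <- if (width == 2) expand.grid(dy = 0:1, dx = 0:1)
          else expand.grid(dy = -1:1, dx = -1:1)
  out <- lapply(seq_len(nrow(offs)), function(i)
    cbind(coords[, 1] + offs$dy[i], coords[, 2] + offs$dx[i]))
  unique(do.call(rbind, out))
}

coords_to_index <- function(coords, ny, nx) {
  keep <- coords[, 1] >= 1 & coords[, 1] <= ny &
          coords[, 2] >= 1 & coords[, 2] <= nx
  coords <- coords[keep, , drop = FALSE]
  as.integer(coords[, 1] + (coords[, 2] - 1L) * ny)
}

#' Generate one synthetic organoid-section field
#'
#' @param params [synth_params()].
#' @param render if `FALSE`, skip pixel rendering and return ground truth
#'   only (used for fast statistical simulation at the feature level).
#' @return list with `image` (an [image_stack()]; `NULL` when
#'   `render = FALSE`) and `truth` (ground truth: per-cell records, nucleus
#'   pixel sets, and per-image totals aggregated from the records).
#' @export
generate_section <- function(params, render = TRUE) {
  validate_synth_params(params)
  withr::with_seed(params$seed, generate_section_impl(params, render))
}

generate_section_impl <- function(p, render) {
  shape <- p$image_shape
  is3d <- length(shape) == 3L
  nz <- if (is3d) shape[1] else 1L
  ny <- if (is3d) shape[2] else shape[1]
  nx <- if (is3d) shape[3] else shape[2]
  rmin <- p$nucleus_radius_range[1]; rmax <- p$nucleus_radius_range[2]
  n <- p$n_cells

  centers <- place_cells(c(ny, nx), n, rmax, p$cell_gap)
  pyk <- if (n) runif(n) < p$pyknotic_fraction else logical(0)
  radius <- ifelse(pyk, rmin, runif(n, rmin, rmax))
  zplane <- if (n) sample.int(nz, n, replace = TRUE) else integer(0)

  # section-level jitter on marker prevalences (organoid variability)
  sec_frac <- vapply(p$marker_profiles, function(mp)
    min(1, max(0, mp$positive_fraction +
                    if (p$section_jitter_sd > 0)
                      rnorm(1, 0, p$section_jitter_sd) else 0)),
    numeric(1))
  names(sec_frac) <- vapply(p$marker_profiles, `[[`, "", "name")
  loc <- vapply(p$marker_profiles, `[[`, "", "localization")
  names(loc) <- names(sec_frac)

  # positivity: per-cell Bernoulli counts; cytoplasmic+neurite markers are
  # additionally clustered in space (positives occupy the image periphery,
  # emulating the niche organization of organoid sections: neuron-rich rim,
  # progenitor core) so that neurite signal stays near positive cells
  flags <- matrix(FALSE, nrow = n, ncol = length(p$marker_profiles),
                  dimnames = list(NULL, names(sec_frac)))
  if (n > 0) {
    axis <- runif(1, 0, 2 * pi)
    proj <- centers[, 1] * sin(axis) + centers[, 2] * cos(axis)
    for (m in names(sec_frac)) {
      pos <- !pyk & (runif(n) < sec_frac[[m]])
      if (loc[[m]] == "cytoplasmic+neurite" && p$spatial_noise < Inf) {
        k <- sum(pos)
        score <- proj + rnorm(n, 0, p$spatial_noise * max(ny, nx))
        score[pyk] <- -Inf
        pos <- logical(n)
        pos[order(score, decreasing = TRUE)[seq_len(k)]] <- TRUE
      }
      flags[, m] <- pos
    }
  }

  # per-cell shape/intensity draws happen in both modes (identical RNG
  # stream); the pixel geometry itself is only materialized when rendering
  ecc <- runif(n, 0.75, 1)
  theta <- runif(n, 0, pi)
  base_int <- runif(n, p$nucleus_intensity_range[1],
                    p$nucleus_intensity_range[2])
  nucleus_px <- if (render) {
    lapply(seq_len(n), function(i)
      ellipse_pixels(centers[i, 1], centers[i, 2],
                     radius[i], radius[i] * ecc[i], theta[i], ny, nx))
  } else NULL

  # neurite trees for cytoplasmic+neurite markers (drawn topology recorded)
  np <- p$neurite_params
  cyto <- vapply(p$marker_profiles, function(mp)
    mp$localization == "cytoplasmic+neurite", logical(1))
  tree_nodes <- integer(n); tree_links <- integer(n)
  trees <- vector("list", n)
  # neurites project into the neuron-rich side of the niche axis
  trunk_bias <- if (n > 0 && p$spatial_noise < Inf) axis else NULL
  for (i in seq_len(n)) {
    pos_any_cyto <- any(flags[i, cyto, drop = FALSE])
    if (!pos_any_cyto) next
    k <- rpois(1, np$mean_primary)
    if (k == 0) next
    tr <- vector("list", k)
    for (j in seq_len(k)) {
      a0 <- if (is.null(trunk_bias)) runif(1, 0, 2 * pi)
            else trunk_bias + runif(1, -0.6 * pi, 0.6 * pi)
      soma_r <- radius[i] + 3
      tr[[j]] <- draw_tree(centers[i, 1] + soma_r * sin(a0),
                           centers[i, 2] + soma_r * cos(a0), a0, np)
      tree_nodes[i] <- tree_nodes[i] + tr[[j]]$n_nodes
      tree_links[i] <- tree_links[i] + tr[[j]]$n_links
    }
    trees[[i]] <- do.call(rbind, lapply(tr, `[[`, "coords"))
  }

  cells <- data.frame(id = seq_len(n),
                      y = centers[, 1], x = centers[, 2], z = zplane,
                      radius = radius, pyknotic = pyk,
                      stringsAsFactors = FALSE)
  for (m in colnames(flags)) cells[[m]] <- flags[, m]
  cells$n_nodes <- tree_nodes
  cells$n_links <- tree_links

  truth <- list(cells = cells, nucleus_pixels = nucleus_px,
                totals = truth_totals(cells))
  image <- if (render)
    render_section(p, cells, nucleus_px, trees, base_int,
                   ny, nx, nz) else NULL
  list(image = image, truth = truth)
}

# per-image totals aggregated from the per-cell records
truth_totals <- function(cells) {
  viable <- !cells$pyknotic
  nv <- sum(viable)
  marker_cols <- setdiff(names(cells),
                         c("id", "y", "x", "z", "radius", "pyknotic",
                           "n_nodes", "n_links"))
  frac <- function(flag) if (nv > 0) sum(flag & viable) / nv else NA_real_
  totals <- list(n_cells = nrow(cells), n_viable = nv,
                 n_pyknotic = sum(cells$pyknotic),
                 n_nodes = sum(cells$n_nodes), n_links = sum(cells$n_links))
  for (m in marker_cols) totals[[paste0(m, "_fraction")]] <- frac(cells[[m]])
  if (all(c("th", "foxa2") %in% marker_cols)) {
    totals$th_foxa2_count <- sum(cells$th & cells$foxa2 & viable)
    totals$th_neg_foxa2_count <- sum(!cells$th & cells$foxa2 & viable)
    totals$th_foxa2_fraction <- frac(cells$th & cells$foxa2)
    totals$th_neg_foxa2_fraction <- frac(!cells$th & cells$foxa2)
  }
  totals
}

render_section <- function(p, cells, nucleus_px, trees, base_int,
                           ny, nx, nz) {
  n <- nrow(cells)
  blank <- function() matrix(0, ny, nx)
  plane_of <- function(i) cells$z[i]

  hoechst <- replicate(nz, blank(), simplify = FALSE)
  for (i in seq_len(n)) {
    gain <- if (cells$pyknotic[i]) p$pyknotic_intensity_gain else 1
    pl <- plane_of(i)
    hoechst[[pl]][nucleus_px[[i]]] <-
      pmax(hoechst[[pl]][nucleus_px[[i]]], base_int[i] * gain)
  }

  channels <- list(hoechst = hoechst)
  for (mp in p$marker_profiles) {
    ch <- replicate(nz, blank(), simplify = FALSE)
    pos <- cells[[mp$name]]
    if (mp$localization == "nuclear") {
      for (i in which(pos)) {
        pl <- plane_of(i)
        ch[[pl]][nucleus_px[[i]]] <-
          pmax(ch[[pl]][nucleus_px[[i]]], mp$intensity)
      }
    } else {
      w <- p$neurite_params$width
      for (i in which(pos)) {
        pl <- plane_of(i)
        soma <- ellipse_pixels(cells$y[i], cells$x[i],
                               cells$radius[i] + 1, cells$radius[i] + 1,
                               0, ny, nx)
        ch[[pl]][soma] <- pmax(ch[[pl]][soma], mp$intensity)
        if (!is.null(trees[[i]])) {
          idx <- coords_to_index(thicken(trees[[i]], w), ny, nx)
          ch[[pl]][idx] <- pmax(ch[[pl]][idx], mp$intensity * 0.9)
        }
      }
    }
    channels[[mp$name]] <- ch
  }

  # optics + read-out noise, then quantization to the 16-bit storage grid
  channels <- lapply(channels, function(ch) {
    planes <- lapply(ch, function(m) {
      if (p$psf_sigma > 0) m <- gaussian_blur_cpp(m, p$psf_sigma)
      if (p$noise_sigma > 0) m <- m + rnorm(length(m), 0, p$noise_sigma)
      quantize16(m)
    })
    if (nz == 1L) planes[[1]] else simplify2array(planes)
  })
  image_stack(channels)
}

#' Multichannel image container
#'
#' @param channels named list of numeric matrices (Y, X) or 3D arrays
#'   (Y, X, Z), one per channel role; a `hoechst` channel is required.
#' @param pixel_size physical size of one pixel (optional, microns).
#' @return an `image_stack` object.
#' @export
image_stack <- function(channels, pixel_size = NULL) {
  stopifnot(is.list(channels), !is.null(names(channels)))
  names(channels) <- tolower(names(channels))
  if (!"hoechst" %in% names(channels))
    stop("an image stack requires a 'hoechst' channel")
  dims <- lapply(channels, dim)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    stop("all channels must share one shape")
  structure(list(channels = channels, pixel_size = pixel_size),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat("image_stack:", paste(d, collapse = " x "),
      "| channels:", paste(names(x$channels), collapse = ", "), "\n")
  invisible(x)
}

#' Synthetic neurite mask with known topology
#'
#' Draws one or more neurite trees (no soma) into an otherwise empty mask
#' and reports the drawn bifurcation (node) and segment (link) counts;
#' intended for validating skeleton-based topology recovery.
#'
#' @param shape `c(y, x)` mask size.
#' @param neurite_params as in [synth_params()].
#' @param n_trees number of independent trees.
#' @param seed integer seed.
#' @return list with `mask` (logical matrix), `n_nodes`, `n_links`.
#' @export
synth_neurite_mask <- function(shape = c(128, 128),
                               neurite_params = list(
                                 branch_length_range = c(8, 14),
                                 bifurcation_prob = 0.5, max_depth = 3,
                                 width = 1),
                               n_trees = 1, seed = 1) {
  withr::with_seed(seed, {
    ny <- shape[1]; nx <- shape[2]
    mask <- matrix(FALSE, ny, nx)
    nodes <- 0L; links <- 0L
    for (t in seq_len(n_trees)) {
      y0 <- runif(1, ny * 0.4, ny * 0.6)
      x0 <- runif(1, nx * 0.4, nx * 0.6)
      tr <- draw_tree(y0, x0, runif(1, 0, 2 * pi), neurite_params)
      idx <- coords_to_index(thicken(tr$coords, neurite_params$width %||% 1),
                             ny, nx)
      mask[idx] <- TRUE
      nodes <- nodes + tr$n_nodes; links <- links + tr$n_links
    }
    list(mask = mask, n_nodes = nodes, n_links = links)
  })
}
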