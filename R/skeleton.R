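#' Skeletonize a TH mask
#'
#' Topology-preserving Zhang-Suen thinning to a 1-pixel-wide skeleton,
#' optionally followed by spur pruning: terminal branches shorter than
#' `prune` pixels that end at a junction are removed (thinning artifacts on
#' jagged mask boundaries); free-standing short paths are kept.
#'
#' @param th a `marker_mask`, or a logical/binary matrix.
#' @param prune spur length cutoff in pixels (0 disables pruning).
#' @return a `skeleton_graph` list with `skeleton` (logical matrix); node
#'   and link counts are filled by [count_nodes_links()].
#' @export
skeletonize <- function(th, prune = 3) {
  mask <- if (inherits(th, "marker_mask")) th$mask else th
  m <- as_binary_matrix(mask)
  skel <- thin_cpp(m) > 0
  if (prune > 0) skel <- prune_spurs(skel, prune)
  structure(list(skeleton = skel, n_nodes = NULL, n_links = NULL),
            class = "skeleton_graph")
}

# remove terminal chains shorter than min_len that attach to a junction
prune_spurs <- function(skel, min_len) {
  if (!any(skel)) return(skel)
  deg <- neighbor_count_cpp(as_binary_matrix(skel))
  ny <- nrow(skel)
  ends <- which(skel & deg == 1)
  if (!length(ends)) return(skel)
  out <- skel
  for (e in ends) {
    path <- e
    prev <- NA_integer_
    cur <- e
    repeat {
      nb <- pixel_neighbors(cur, ny, length(skel))
      nb <- nb[skel[nb]]
      nb <- setdiff(nb, c(prev, path))
      if (length(nb) == 0L) break            # free-standing path: keep
      if (any(deg[nb] >= 3)) {               # reached a junction
        if (length(path) < min_len) out[path] <- FALSE
        break
      }
      if (length(path) >= min_len) break     # long enough: keep
      prev <- cur
      cur <- nb[1]
      path <- c(path, cur)
    }
  }
  out
}

# linear indices of the 8-neighbors of linear index i in an ny-row matrix
pixel_neighbors <- function(i, ny, n) {
  r <- ((i - 1L) %% ny) + 1L
  offs <- c(-ny - 1L, -ny, -ny + 1L, -1L, 1L, ny - 1L, ny, ny + 1L)
  nb <- i + offs
  keep <- nb >= 1L & nb <= n
  # row wrap guard: neighbor row must be within +-1 of r
  rr <- ((nb - 1L) %% ny) + 1L
  nb[keep & abs(rr - r) <= 1L]
}

#' Count bifurcation nodes and branch links of a skeleton
#'
#' A skeleton pixel is a branch pixel iff it has three or more skeleton
#' neighbors (8-connectivity); 8-adjacent branch pixels are merged into one
#' node (thinning produces small junction clusters, while the biological
#' quantity is the bifurcation). Links are the maximal skeleton paths
#' between nodes and/or degree-1 tips — equivalently, the connected
#' components of the skeleton after the branch pixels are removed (a pure
#' cycle counts as one link).
#'
#' @param sk `skeleton_graph` from [skeletonize()], or a skeleton matrix.
#' @return the `skeleton_graph` with `n_nodes`, `n_links`, and label
#'   matrices `node_labels`, `link_labels` filled.
#' @export
count_nodes_links <- function(sk) {
  skel <- if (inherits(sk, "skeleton_graph")) sk$skeleton else sk > 0
  m <- as_binary_matrix(skel)
  deg <- neighbor_count_cpp(m)
  junction <- m == 1L & deg >= 3L
  node_labels <- label_cc_cpp(as_binary_matrix(junction), 8L)
  link_labels <- label_cc_cpp(as_binary_matrix(m == 1L & !junction), 8L)
  structure(list(skeleton = m == 1L,
                 n_nodes = max(node_labels), n_links = max(link_labels),
                 node_labels = node_labels, link_labels = link_labels),
            class = "skeleton_graph")
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat("skeleton_graph:", sum(x$skeleton), "px",
      if (!is.null(x$n_nodes))
        paste0("| ", x$n_nodes, " nodes, ", x$n_links, " links"), "\n")
  invisible(x)
}
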