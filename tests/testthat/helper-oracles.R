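# Independent oracles used across the suite. These deliberately use
# different machinery from the package internals (igraph adjacency graphs,
# plain R flood fill, textbook sums-of-squares formulas).

# skeleton node/link counts from an explicit pixel-adjacency graph:
# vertices = skeleton pixels, edges = 8-neighbor pairs; junction vertices
# have graph degree >= 3; nodes = connected clusters of junction vertices,
# links = connected components after deleting the junction vertices.
oracle_skeleton_counts <- function(skel) {
  px <- which(skel, arr.ind = TRUE)
  n <- nrow(px)
  if (n == 0) return(c(nodes = 0L, links = 0L))
  idx <- seq_len(n)
  names(idx) <- paste(px[, 1], px[, 2])
  from <- integer(0); to <- integer(0)
  for (i in seq_len(n)) {
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0 && dx == 0) next
      j <- idx[paste(px[i, 1] + dy, px[i, 2] + dx)]
      if (!is.na(j) && j > i) { from <- c(from, i); to <- c(to, j) }
    }
  }
  g <- igraph::make_graph(rbind(from, to), n = n, directed = FALSE)
  deg <- igraph::degree(g)
  junc <- which(deg >= 3)
  nodes <- if (length(junc))
    igraph::components(igraph::induced_subgraph(g, junc))$no else 0L
  rest <- setdiff(seq_len(n), junc)
  links <- if (length(rest))
    igraph::components(igraph::induced_subgraph(g, rest))$no else 0L
  c(nodes = nodes, links = links)
}

# plain-R flood-fill component enumeration (queue-based BFS)
oracle_components <- function(mask, connectivity = 8) {
  ny <- nrow(mask); nx <- ncol(mask)
  lab <- matrix(0L, ny, nx)
  offs <- if (connectivity == 8)
    cbind(dy = c(-1, -1, -1, 0, 0, 1, 1, 1), dx = c(-1, 0, 1, -1, 1, -1, 0, 1))
  else cbind(dy = c(-1, 0, 0, 1), dx = c(0, -1, 1, 0))
  k <- 0L
  for (x in seq_len(nx)) for (y in seq_len(ny)) {
    if (!mask[y, x] || lab[y, x] != 0L) next
    k <- k + 1L
    queue <- list(c(y, x)); lab[y, x] <- k
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (o in seq_len(nrow(offs))) {
        y2 <- p[1] + offs[o, 1]; x2 <- p[2] + offs[o, 2]
        if (y2 >= 1 && y2 <= ny && x2 >= 1 && x2 <= nx &&
            mask[y2, x2] && lab[y2, x2] == 0L) {
          lab[y2, x2] <- k
          queue[[length(queue) + 1L]] <- c(y2, x2)
        }
      }
    }
  }
  lab
}

# textbook balanced two-way ANOVA decomposition (equal cell counts)
oracle_balanced_anova <- function(y, A, B) {
  A <- factor(A); B <- factor(B)
  ybar <- mean(y)
  ssA <- sum(tapply(y, A, function(v) length(v) * (mean(v) - ybar)^2))
  ssB <- sum(tapply(y, B, function(v) length(v) * (mean(v) - ybar)^2))
  cellm <- tapply(y, list(A, B), mean)
  r <- length(y) / (nlevels(A) * nlevels(B))
  am <- tapply(y, A, mean); bm <- tapply(y, B, mean)
  ssAB <- r * sum((sweep(sweep(cellm, 1, am), 2, bm) + ybar)^2)
  ssE <- sum((y - cellm[cbind(A, B)])^2)
  dfA <- nlevels(A) - 1; dfB <- nlevels(B) - 1
  dfAB <- dfA * dfB
  dfE <- length(y) - nlevels(A) * nlevels(B)
  list(ss = c(A = ssA, B = ssB, AB = ssAB, E = ssE),
       F = c(A = (ssA / dfA) / (ssE / dfE),
             B = (ssB / dfB) / (ssE / dfE),
             AB = (ssAB / dfAB) / (ssE / dfE)))
}

# tiny helper: a filled disk mask
disk_mask <- function(ny, nx, cy, cx, r) {
  outer(seq_len(ny), seq_len(nx),
        function(y, x) (y - cy)^2 + (x - cx)^2 <= r^2)
}

# balanced random two-factor dataset in feature-table shape
balanced_toy <- function(seed, g = c("H", "P"), d = c(10, 35), r = 4) {
  set.seed(seed)
  df <- expand.grid(group = g, day = d, rep = seq_len(r))
  df$y <- rnorm(nrow(df), 1 + 0.4 * (df$group == df$group[1]) +
                  0.2 * (df$day == d[2]))
  df$line <- "L"; df$section_id <- seq_len(nrow(df))
  df
}
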