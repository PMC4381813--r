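#' Inverse-contact adjacency graph of a normalized matrix
#'
#' Builds the weighted graph used for 3D reconstruction: nodes are bins,
#' and an edge joins bins i and j (i != j) whenever the normalized contact
#' m[i, j] > 0, with weight 1 / m[i, j] — strong contacts become short
#' edges. The diagonal is ignored. Bins with no off-diagonal contacts
#' become isolated nodes and are reported.
#'
#' @param cm a \code{contact_matrix} (state \code{"scn"}).
#' @return igraph weighted undirected graph; vertex names are bin indices.
#' @export
contacts_to_graph <- function(cm) {
  stopifnot(inherits(cm, "contact_matrix"))
  m <- cm$m
  if (any(m < 0)) stopf("contact matrix must be non-negative")
  n <- nrow(m)
  idx <- which(upper.tri(m) & m > 0, arr.ind = TRUE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(idx[, 1]), to = as.character(idx[, 2]),
               weight = 1 / m[idx]),
    directed = FALSE,
    vertices = data.frame(name = as.character(seq_len(n))))
  iso <- which(igraph::degree(g) == 0)
  g <- igraph::set_graph_attr(g, "isolated", as.integer(iso))
  g
}

#' All-pairs shortest-path distance matrix
#'
#' Converts the inverse-contact graph into a metric: d[i, j] is the length
#' of the shortest path between bins i and j over the non-negative edge
#' weights (the Floyd–Warshall contract; pairs in different components are
#' Inf and structures are computed per component).
#'
#' @param g weighted igraph graph (non-negative weights).
#' @return Symmetric numeric matrix with zero diagonal, class
#'   \code{"dist_matrix"}.
#' @export
shortest_path_distances <- function(g) {
  w <- igraph::E(g)$weight
  if (!is.null(w) && any(w < 0)) stopf("negative edge weights")
  d <- igraph::distances(g, weights = w, algorithm = "dijkstra")
  num <- suppressWarnings(as.integer(rownames(d)))
  if (!anyNA(num)) d <- d[order(num), order(num)]
  class(d) <- c("dist_matrix", class(d))
  d
}

#' 3D embedding of a distance matrix by classical scaling
#'
#' Distance-geometry reconstruction: the squared-distance matrix is double
#' centered, the three leading non-negative eigenpairs are taken, and
#' coordinates are eigenvector * sqrt(eigenvalue). Negative eigenvalues
#' (non-Euclidean input) are truncated to zero and their total magnitude
#' reported as a diagnostic. The orientation is canonicalized — axes
#' ordered by eigenvalue and each flipped so its third moment is
#' non-negative — so runs are reproducible. The normalized RMS deviation
#' between input and embedded distances is reported as \code{stress}.
#'
#' @param d symmetric distance matrix, finite on one component.
#' @param bins optional bin-label data.frame carried into the result.
#' @return A \code{structure3d}: list with \code{coords} (n x 3),
#'   \code{eigenvalues} (top 3), \code{negative_mass}, \code{stress},
#'   \code{bins}, \code{track}.
#' @export
embed_3d <- function(d, bins = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 4) stopf("need at least 4 points to embed in 3D")
  if (any(!is.finite(d)))
    stopf("distance matrix must be finite on the embedded component")
  if (all(d == 0)) stopf("all distances are zero")
  if (max(abs(d - t(d))) > 1e-8) stopf("distance matrix must be symmetric")
  D2 <- d^2
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% D2 %*% J
  B <- (B + t(B)) / 2
  eg <- eigen(B, symmetric = TRUE)
  ev <- eg$values
  neg_mass <- sum(abs(ev[ev < 0]))
  lam <- pmax(ev[1:3], 0)
  lam[lam < ev[1] * 1e-12] <- 0   # numerical-noise eigenvalues
  X <- eg$vectors[, 1:3, drop = FALSE] %*% diag(sqrt(lam), 3)
  # canonical orientation: non-negative third moment on every axis
  for (k in 1:3) {
    m3 <- sum(X[, k]^3)
    if (m3 < 0) X[, k] <- -X[, k]
  }
  dd <- as.matrix(dist(X))
  ut <- upper.tri(d)
  stress <- sqrt(sum((dd[ut] - d[ut])^2) / sum(d[ut]^2))
  structure(list(coords = X, eigenvalues = lam, negative_mass = neg_mass,
                 stress = stress, bins = bins, track = NULL),
            class = "structure3d")
}

#' @export
print.structure3d <- function(x, ...) {
  cat(sprintf(
    "<structure3d> %d bins; eigenvalues %.3g/%.3g/%.3g; stress %.3g\n",
    nrow(x$coords), x$eigenvalues[1], x$eigenvalues[2], x$eigenvalues[3],
    x$stress))
  invisible(x)
}

#' Embed a normalized contact matrix, per connected component
#'
#' Convenience wrapper chaining \code{\link{contacts_to_graph}},
#' \code{\link{shortest_path_distances}} and \code{\link{embed_3d}}.
#' Disconnected components are embedded independently and returned as a
#' list (largest first).
#'
#' @param cm an SCN \code{contact_matrix}.
#' @return A list of \code{structure3d} objects, one per component with
#'   >= 4 bins; each carries the bin labels of its component.
#' @export
embed_matrix <- function(cm) {
  g <- contacts_to_graph(cm)
  comp <- igraph::components(g)
  out <- list()
  for (ci in order(comp$csize, decreasing = TRUE)) {
    vids <- which(comp$membership == ci)
    if (length(vids) < 4) next
    sg <- igraph::induced_subgraph(g, vids)
    d <- shortest_path_distances(sg)
    binidx <- as.integer(rownames(d))
    out[[length(out) + 1L]] <-
      embed_3d(unclass(d), bins = cm$bins[binidx, , drop = FALSE])
  }
  if (!length(out)) stopf("no component with >= 4 bins to embed")
  out
}

#' Attach a per-bin scalar track to a structure
#'
#' Stores a scalar (e.g. read coverage) per embedded bin, exported with
#' the coordinates for coloring. The track must match the embedded bins —
#' after any masking, it is supplied post-masking.
#'
#' @param s a \code{structure3d}.
#' @param track numeric vector, one value per embedded bin.
#' @return The \code{structure3d} with \code{track} set.
#' @export
attach_track <- function(s, track) {
  stopifnot(inherits(s, "structure3d"))
  if (length(track) != nrow(s$coords))
    stopf("track length (%d) != number of embedded bins (%d)",
          length(track), nrow(s$coords))
  s$track <- as.numeric(track)
  s
}

#' Ring diagnostics of an embedded replicon
#'
#' Quantifies whether a replicon's embedding closes into a ring: with bins
#' in genomic order, reports the Euclidean gaps between genomically
#' adjacent bins, the ratio of the maximum to the median gap, and the
#' closure gap |x_first - x_last| relative to the median gap. A circular
#' chromosome embeds with closure_ratio near 1; a linear one leaves a
#' large closure gap.
#'
#' @param s a \code{structure3d} whose coords rows are bins of one
#'   replicon in genomic order (or use \code{order} to reorder).
#' @param order optional integer permutation putting bins in genomic
#'   order.
#' @return list: \code{gaps}, \code{median_gap}, \code{max_ratio}
#'   (max adjacent gap / median), \code{closure_gap},
#'   \code{closure_ratio} (closure gap / median gap).
#' @export
ring_diagnostics <- function(s, order = NULL) {
  X <- s$coords
  if (!is.null(order)) X <- X[order, , drop = FALSE]
  n <- nrow(X)
  if (n < 4) stopf("need >= 4 bins for ring diagnostics")
  gaps <- sqrt(rowSums((X[-1, , drop = FALSE] -
                          X[-n, , drop = FALSE])^2))
  closure <- sqrt(sum((X[1, ] - X[n, ])^2))
  med <- median(gaps)
  list(gaps = gaps, median_gap = med,
       max_ratio = max(c(gaps, closure)) / med,
       closure_gap = closure, closure_ratio = closure / med)
}

#' Export a 3D structure
#'
#' Writes a TSV (replicon, start, end, x, y, z, track) and optionally a
#' minimal XYZ-style file for molecular viewers (one pseudo-atom per bin).
#'
#' @param s a \code{structure3d}.
#' @param path TSV path.
#' @param xyz optional XYZ path.
#' @export
write_structure <- function(s, path, xyz = NULL) {
  df <- data.frame(
    replicon = s$bins$replicon %||% NA, start = s$bins$start %||% NA,
    end = s$bins$end %||% NA,
    x = s$coords[, 1], y = s$coords[, 2], z = s$coords[, 3],
    track = if (is.null(s$track)) NA_real_ else s$track)
  write_tsv(df, path)
  if (!is.null(xyz)) {
    con <- file(xyz, "w")
    writeLines(as.character(nrow(s$coords)), con)
    writeLines("genome structure", con)
    writeLines(sprintf("C %.6f %.6f %.6f", s$coords[, 1], s$coords[, 2],
                       s$coords[, 3]), con)
    close(con)
  }
  invisible(path)
}
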