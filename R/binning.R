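#' Split contigs into equal-sized chunks
#'
#' Contigs longer than \code{split_threshold} (default 2,500 bp) are
#' divided into k = floor(length / threshold) equal-length chunks (lengths
#' within a contig differ by at most 1 bp); shorter contigs form a single
#' chunk. Chunking equalizes node sizes in the contact graph, since large
#' contigs accumulate more contacts than small ones.
#'
#' @param contig_lengths named integer vector of contig lengths.
#' @param split_threshold minimum length for splitting, bp.
#' @return A \code{chunk_set}: data.frame with columns \code{chunk}
#'   (global index), \code{node} ("contig.k" name), \code{contig},
#'   \code{k}, \code{start}, \code{end}, \code{length}.
#' @export
chunk_contigs <- function(contig_lengths, split_threshold = 2500) {
  stopifnot(all(contig_lengths >= 1))
  nm <- names(contig_lengths)
  if (is.null(nm)) stopf("contig lengths must be named")
  rows <- vector("list", length(contig_lengths))
  for (i in seq_along(contig_lengths)) {
    L <- contig_lengths[[i]]
    k <- max(1L, L %/% as.integer(split_threshold))
    bounds <- as.integer(round(seq(0, L, length.out = k + 1)))
    rows[[i]] <- data.frame(
      contig = nm[i], k = seq_len(k),
      start = bounds[-(k + 1)], end = bounds[-1],
      stringsAsFactors = FALSE)
  }
  ch <- do.call(rbind, rows)
  ch <- cbind(chunk = seq_len(nrow(ch)),
              node = paste0(ch$contig, ".", ch$k), ch)
  ch$length <- ch$end - ch$start
  rownames(ch) <- NULL
  structure(ch, class = c("chunk_set", "data.frame"))
}

# (contig, position) -> global chunk index.
chunk_of <- function(chunks, contig, position) {
  out <- integer(length(position))
  for (ct in unique(contig)) {
    i <- which(contig == ct)
    sub <- chunks[chunks$contig == ct, ]
    j <- findInterval(position[i], sub$start)
    j[j < 1L] <- 1L; j[j > nrow(sub)] <- nrow(sub)
    out[i] <- sub$chunk[j]
  }
  out
}

#' Build the chunk-level contact graph
#'
#' Edge weight between two chunks is the number of pairs joining them;
#' intra-chunk pairs are discarded (no self-loops). Chunks with no
#' inter-chunk contact remain as isolated nodes. Pairs referencing a
#' contig absent from the chunk set are rejected and counted.
#'
#' @param pairs a \code{pair_table} whose refs are contig names.
#' @param chunks a \code{\link{chunk_contigs}} result.
#' @return An igraph weighted undirected graph; vertex attributes
#'   \code{name} (chunk node), \code{contig}, \code{length}; graph
#'   attribute \code{rejected}.
#' @export
build_graph <- function(pairs, chunks) {
  known <- unique(chunks$contig)
  ok <- pairs$ref1 %in% known & pairs$ref2 %in% known
  rejected <- sum(!ok)
  p <- pairs[ok, , drop = FALSE]
  u <- chunk_of(chunks, p$ref1, p$pos1)
  v <- chunk_of(chunks, p$ref2, p$pos2)
  keep <- u != v
  lo <- pmin(u[keep], v[keep]); hi <- pmax(u[keep], v[keep])
  nch <- nrow(chunks)
  key <- (as.numeric(lo) - 1) * nch + hi
  tab <- table(key)
  k <- as.numeric(names(tab))
  e_lo <- floor((k - 1) / nch) + 1
  e_hi <- ((k - 1) %% nch) + 1
  g <- igraph::graph_from_data_frame(
    data.frame(from = chunks$node[e_lo], to = chunks$node[e_hi],
               weight = as.numeric(tab)),
    directed = FALSE,
    vertices = data.frame(name = chunks$node, contig = chunks$contig,
                          length = chunks$length,
                          stringsAsFactors = FALSE))
  g <- igraph::set_graph_attr(g, "rejected", rejected)
  g
}

#' Louvain community detection on the contact graph
#'
#' Modularity optimization over the weighted chunk graph with a resolution
#' parameter; with \code{repeats > 1} the algorithm is run with distinct
#' sub-seeds and the highest-modularity partition returned. Deterministic
#' given \code{seed}. A graph without edges yields one community per node
#' (modularity undefined, reported as NA).
#'
#' @param g weighted igraph graph from \code{\link{build_graph}} (or any
#'   undirected graph).
#' @param resolution resolution parameter r > 0 (default 1); larger values
#'   favour more, smaller communities.
#' @param repeats number of seeded restarts (default 5).
#' @param seed integer seed.
#' @return A \code{partition}: list with \code{membership} (named integer
#'   vector over nodes), \code{modularity}, \code{resolution},
#'   \code{communities} (data.frame community, n_nodes, length).
#' @export
louvain_partition <- function(g, resolution = 1, repeats = 5, seed = 1) {
  stopifnot(resolution > 0, repeats >= 1, igraph::vcount(g) >= 1)
  if (igraph::ecount(g) == 0) {
    memb <- setNames(seq_len(igraph::vcount(g)),
                     igraph::V(g)$name %||% seq_len(igraph::vcount(g)))
    return(new_partition(memb, NA_real_, resolution, g))
  }
  best <- NULL; best_q <- -Inf
  for (rep in seq_len(repeats)) {
    sub <- derive_seed(seed, paste0("louvain", rep))
    cl <- with_seed(sub, igraph::cluster_louvain(g, resolution = resolution))
    q <- max(cl$modularity)
    if (q > best_q) { best_q <- q; best <- cl }
  }
  memb <- igraph::membership(best)
  new_partition(setNames(as.integer(memb), names(memb)), best_q,
                resolution, g)
}

new_partition <- function(membership, modularity, resolution, g = NULL) {
  lens <- if (!is.null(g) && "length" %in%
              igraph::vertex_attr_names(g)) {
    igraph::V(g)$length
  } else rep(NA_real_, length(membership))
  comm <- data.frame(
    community = sort(unique(as.integer(membership))))
  comm$n_nodes <- as.integer(table(membership)[as.character(comm$community)])
  comm$length <- as.numeric(tapply(lens, membership, sum)[
    as.character(comm$community)])
  structure(list(membership = membership, modularity = modularity,
                 resolution = resolution, communities = comm),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("<partition> %d nodes in %d communities (Q=%.4f, r=%g)\n",
              length(x$membership), nrow(x$communities),
              x$modularity, x$resolution))
  invisible(x)
}

#' Reconcile chunk communities into per-contig calls
#'
#' Each contig is assigned to the community holding the majority of its
#' chunk length; the agreement fraction (assigned length / total length)
#' is reported and contigs below \code{min_agreement} (or exact ties) are
#' flagged unattributed (community NA).
#'
#' @param partition a \code{\link{louvain_partition}} result.
#' @param chunks the \code{chunk_set} the partition was computed on.
#' @param min_agreement minimum agreement fraction (default 0.5,
#'   exclusive ties).
#' @return data.frame: contig, community, agreement, length.
#' @export
assign_contigs <- function(partition, chunks, min_agreement = 0.5) {
  memb <- partition$membership[chunks$node]
  if (anyNA(memb)) stopf("partition does not cover all chunks")
  res <- lapply(split(seq_len(nrow(chunks)), chunks$contig), function(i) {
    w <- tapply(chunks$length[i], memb[i], sum)
    tot <- sum(chunks$length[i])
    top <- which(w == max(w))
    if (length(top) > 1L) {
      data.frame(community = NA_integer_, agreement = max(w) / tot,
                 length = tot)
    } else {
      agr <- max(w) / tot
      data.frame(
        community = if (agr >= min_agreement && !(agr == min_agreement &&
          length(top) > 1L)) as.integer(names(w)[top]) else NA_integer_,
        agreement = agr, length = tot)
    }
  })
  out <- do.call(rbind, res)
  out <- cbind(data.frame(contig = names(res), stringsAsFactors = FALSE),
               out)
  out$community[!is.na(out$community) &
                  out$agreement < min_agreement] <- NA_integer_
  rownames(out) <- NULL
  out
}

#' Filter communities by total length
#'
#' Communities whose member contigs total less than \code{min_length} bp
#' are marked non-significant; a summary (count, total and median size of
#' the significant communities) is attached.
#'
#' @param contig_table an \code{\link{assign_contigs}} result.
#' @param min_length minimum community length in bp.
#' @return data.frame: community, n_contigs, length, significant; with
#'   attribute \code{"summary"}.
#' @export
filter_communities <- function(contig_table, min_length = 0) {
  ct <- contig_table[!is.na(contig_table$community), , drop = FALSE]
  if (nrow(ct) == 0) {
    out <- data.frame(community = integer(0), n_contigs = integer(0),
                      length = numeric(0), significant = logical(0))
    attr(out, "summary") <- list(n_significant = 0L, total = 0,
                                 median = NA_real_)
    return(out)
  }
  len <- tapply(ct$length, ct$community, sum)
  out <- data.frame(community = as.integer(names(len)),
                    n_contigs = as.integer(table(ct$community)),
                    length = as.numeric(len))
  out$significant <- out$length >= min_length
  sig <- out$length[out$significant]
  attr(out, "summary") <- list(n_significant = sum(out$significant),
                               total = sum(sig),
                               median = if (length(sig)) median(sig)
                                        else NA_real_)
  out
}

#' Export a contact graph for external visualization
#'
#' Writes a weighted edge-list TSV (node1, node2, weight) and, when
#' \code{graphml} is given, a GraphML file suitable for force-directed
#' layout tools.
#'
#' @param g igraph graph.
#' @param path edge-list TSV path.
#' @param graphml optional GraphML path.
#' @export
write_graph_tsv <- function(g, path, graphml = NULL) {
  el <- igraph::as_data_frame(g, what = "edges")
  names(el)[1:2] <- c("node1", "node2")
  write_tsv(el, path)
  if (!is.null(graphml)) igraph::write_graph(g, graphml, format = "graphml")
  invisible(path)
}
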