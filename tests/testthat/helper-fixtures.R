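# Shared fixtures and independent oracles, built in code at test time.

# Bare contact matrix over one replicon, unit bins.
toy_cm <- function(m, state = "raw", replicon = "r") {
  n <- nrow(m)
  meta3cr:::contact_matrix(
    m, data.frame(bin = seq_len(n), replicon = replicon,
                  start = seq_len(n) - 1L, end = seq_len(n),
                  stringsAsFactors = FALSE),
    state = state)
}

# Minimal pair table; label columns optional.
toy_pairs <- function(ref1, pos1, ref2, pos2,
                      strand1 = "+", strand2 = "-",
                      species1 = NULL, species2 = NULL) {
  df <- data.frame(ref1 = ref1, pos1 = pos1,
                   strand1 = rep_len(strand1, length(ref1)),
                   ref2 = ref2, pos2 = pos2,
                   strand2 = rep_len(strand2, length(ref1)),
                   stringsAsFactors = FALSE)
  if (!is.null(species1)) {
    df$label_species1 <- species1
    df$label_replicon1 <- ref1
    df$label_pos1 <- pos1
    df$label_species2 <- species2
    df$label_replicon2 <- ref2
    df$label_pos2 <- pos2
  }
  class(df) <- c("pair_table", "data.frame")
  df
}

# Exhaustive shortest-path oracle: enumerate every simple path.
# Independent of the package's graph machinery; only for tiny graphs.
brute_shortest_paths <- function(n, edges) {
  # edges: data.frame(from, to, weight), undirected
  adj <- vector("list", n)
  for (k in seq_len(nrow(edges))) {
    a <- edges$from[k]; b <- edges$to[k]; w <- edges$weight[k]
    adj[[a]] <- rbind(adj[[a]], c(b, w))
    adj[[b]] <- rbind(adj[[b]], c(a, w))
  }
  d <- matrix(Inf, n, n); diag(d) <- 0
  walk <- function(v, target, visited, len) {
    if (v == target) { d[visited[1], target] <<- min(d[visited[1], target], len); return() }
    if (!is.null(adj[[v]])) for (k in seq_len(nrow(adj[[v]]))) {
      nxt <- adj[[v]][k, 1]
      if (!(nxt %in% visited)) walk(nxt, target, c(visited, nxt),
                                    len + adj[[v]][k, 2])
    }
  }
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
    walk(i, j, i, 0)
  d
}

# Random connected-ish weighted graph on <= 7 nodes as an igraph object
# plus its edge list (for the oracle).
random_small_graph <- function(seed) {
  set.seed(seed)
  n <- sample(3:7, 1)
  full <- t(combn(n, 2))
  keep <- runif(nrow(full)) < 0.6
  if (!any(keep)) keep[sample(nrow(full), 1)] <- TRUE
  edges <- data.frame(from = full[keep, 1], to = full[keep, 2],
                      weight = round(runif(sum(keep), 0.1, 5), 3))
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges$from),
               to = as.character(edges$to), weight = edges$weight),
    directed = FALSE,
    vertices = data.frame(name = as.character(seq_len(n))))
  list(g = g, n = n, edges = edges)
}

# Planted-partition benchmark graph: 3 blocks of 50 nodes.
planted_partition_graph <- function(seed, p_in = 0.3, p_out = 0.005) {
  set.seed(seed)
  n <- 150
  block <- rep(1:3, each = 50)
  full <- t(combn(n, 2))
  same <- block[full[, 1]] == block[full[, 2]]
  p <- ifelse(same, p_in, p_out)
  keep <- runif(nrow(full)) < p
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(full[keep, 1]),
               to = as.character(full[keep, 2]), weight = 1),
    directed = FALSE,
    vertices = data.frame(name = as.character(seq_len(n))))
  list(g = g, truth = block)
}

# F'-like host: circular chromosome + plasmid carrying a chromosomal copy.
fprime_scenario <- function(seed, n_pairs = 400000L) {
  cfg <- community_config(
    list(species_config("host",
                        list(replicon_config("chr", 500000L, TRUE),
                             replicon_config("plasmid", 200000L, TRUE)))),
    duplication = list(species = "host", src_replicon = "chr",
                       src_start = 300000L, src_end = 360000L,
                       dst_replicon = "plasmid", dst_start = 20000L))
  g <- simulate_genomes(cfg, seed)
  lib <- library_config(n_pairs = n_pairs, p_chimera = 0,
                        p_trans_replicon = 0.1)
  p <- simulate_pairs(g, lib, seed = seed + 1000L)
  scheme <- bp_bins(c(chr = 500000L, plasmid = 200000L), 5000)
  list(genomes = g, pairs = p, scheme = scheme,
       dup = c(start = 300000L, end = 360000L), bin = 5000L)
}
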