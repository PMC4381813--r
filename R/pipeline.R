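#' Default configuration of a synthetic meta3C run
#'
#' A three-species bacterial mix (1 Mb; 1 Mb plus a 0.5 Mb second
#' replicon; 1 Mb — all circular), two million pairs with 80% regular
#' inserts and a 0.37% cross-species background, 10 kb matrix bins,
#' 2.5 kb contig chunks. Every stage derives its own sub-seed from the
#' global seed, so a run is fully reproducible.
#'
#' @param seed global seed.
#' @return A \code{run_config} list.
#' @export
default_run_config <- function(seed = 1) {
  list(
    seed = seed,
    community = community_config(list(
      species_config("speciesA",
                     list(replicon_config("chrA", 1000000L, TRUE))),
      species_config("speciesB",
                     list(replicon_config("chrB1", 1000000L, TRUE),
                          replicon_config("chrB2", 500000L, TRUE))),
      species_config("speciesC",
                     list(replicon_config("chrC", 1000000L, TRUE))))),
    library = list(n_pairs = 2000000L, p_regular = 0.80, alpha = 1.0,
                   p_trans_replicon = 0.05, p_chimera = 0.0037),
    contigs = list(target_n50 = 20000, p_chimeric_join = 0),
    matrix = list(bin_width = 10000L, mode = "basepairs"),
    normalize = list(tol = 1e-6, max_iter = 300L),
    bin = list(chunk_size = 2500L, resolution = 0.1, repeats = 3L,
               min_community_length = 100000),
    features = list(ratio_threshold = 1.6, min_bins = 3, window = 5))
}

#' Read a run configuration from YAML
#'
#' Plain-text key/value configuration with per-species blocks mirroring
#' \code{\link{default_run_config}}; missing sections take the defaults.
#' The seed is mandatory.
#'
#' @param path YAML file.
#' @return A \code{run_config} list.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$seed)) stopf("config must set a seed")
  cfg <- default_run_config(as.integer(y$seed))
  if (!is.null(y$community)) {
    sp <- lapply(y$community$species, function(s) {
      species_config(s$name,
                     lapply(s$replicons, function(r)
                       replicon_config(r$name, r$length,
                                       isTRUE(r$circular))),
                     abundance = s$abundance %||% 1)
    })
    cfg$community <- community_config(sp,
                                      duplication = y$community$duplication,
                                      repeats = y$community$repeats)
  }
  for (sec in c("library", "contigs", "matrix", "normalize", "bin",
                "features")) {
    if (!is.null(y[[sec]]))
      cfg[[sec]] <- utils::modifyList(cfg[[sec]], y[[sec]])
  }
  cfg
}

#' Run the meta3C pipeline
#'
#' Chains the stages simulate -> matrix -> normalize -> bin -> structure
#' -> features -> evaluate over a synthetic community, writing each
#' stage's artifacts (FASTA/TSV only) and a manifest recording every
#' parameter, seed and output checksum. Re-running with an identical
#' configuration reproduces byte-identical outputs. A stage whose
#' upstream artifact is missing stops with an error naming the stage to
#' run first.
#'
#' @param config a \code{run_config}
#'   (\code{\link{default_run_config}} / \code{\link{read_run_config}}).
#' @param outdir output directory (created).
#' @param stages character vector of stages to run, in pipeline order.
#' @return Invisibly, a list with the in-memory stage results
#'   (\code{genomes}, \code{contigs}, \code{pairs}, \code{matrix_raw},
#'   \code{matrix_scn}, \code{partition}, \code{contig_table},
#'   \code{structures}, \code{coverage}, \code{duplications},
#'   \code{report}).
#' @export
run_pipeline <- function(config, outdir,
                         stages = c("simulate", "matrix", "normalize",
                                    "bin", "structure", "features",
                                    "evaluate")) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  st <- list()
  need <- function(obj, stage, producer) {
    if (is.null(obj))
      stopf("missing %s: run the '%s' stage first", stage, producer)
    obj
  }
  seed <- config$seed

  if ("simulate" %in% stages) {
    st$genomes <- simulate_genomes(config$community,
                                   derive_seed(seed, "genomes"))
    st$contigs <- simulate_contigs(
      st$genomes, target_n50 = config$contigs$target_n50,
      p_chimeric_join = config$contigs$p_chimeric_join,
      seed = derive_seed(seed, "contigs"))
    lib <- do.call(library_config, config$library)
    st$pairs <- simulate_pairs(st$genomes, lib,
                               seed = derive_seed(seed, "pairs"))
    st$pairs <- dedup_pairs(st$pairs)
    write_fasta(st$genomes$seqs, file.path(outdir, "genomes.fasta"))
    write_fasta(st$contigs$seqs, file.path(outdir, "contigs.fasta"))
    write_pairs(st$pairs, file.path(outdir, "pairs.tsv"))
    write_tsv(st$contigs$pieces, file.path(outdir, "contig_truth.tsv"))
  }

  if ("matrix" %in% stages) {
    p <- need(st$pairs, "pairs", "simulate")
    g <- need(st$genomes, "genomes", "simulate")
    rl <- setNames(g$replicons$length, g$replicons$replicon)
    st$scheme <- bp_bins(rl, config$matrix$bin_width)
    st$matrix_raw <- build_matrix(p, st$scheme)
    write_contact_matrix_coo(st$matrix_raw,
                             file.path(outdir, "matrix_raw.tsv"))
  }

  if ("normalize" %in% stages) {
    m <- need(st$matrix_raw, "raw matrix", "matrix")
    st$matrix_scn <- scn_normalize(m, tol = config$normalize$tol,
                                   max_iter = config$normalize$max_iter)
    write_contact_matrix_coo(st$matrix_scn,
                             file.path(outdir, "matrix_scn.tsv"))
  }

  if ("bin" %in% stages) {
    p <- need(st$pairs, "pairs", "simulate")
    ct <- need(st$contigs, "contigs", "simulate")
    cpairs <- map_pairs_to_contigs(p, ct)
    chunks <- chunk_contigs(setNames(ct$contigs$length,
                                     ct$contigs$contig),
                            config$bin$chunk_size)
    graph <- build_graph(cpairs, chunks)
    st$partition <- louvain_partition(
      graph, resolution = config$bin$resolution,
      repeats = config$bin$repeats,
      seed = derive_seed(seed, "louvain"))
    st$contig_table <- assign_contigs(st$partition, chunks)
    st$community_table <- filter_communities(
      st$contig_table, config$bin$min_community_length)
    write_graph_tsv(graph, file.path(outdir, "contact_graph.tsv"),
                    graphml = file.path(outdir, "contact_graph.graphml"))
    write_tsv(st$contig_table,
              file.path(outdir, "contig_communities.tsv"))
    write_tsv(st$community_table,
              file.path(outdir, "community_summary.tsv"))
  }

  if ("structure" %in% stages) {
    m <- need(st$matrix_scn, "SCN matrix", "normalize")
    st$structures <- embed_matrix(m)
    for (i in seq_along(st$structures))
      write_structure(st$structures[[i]],
                      file.path(outdir,
                                sprintf("structure_%02d.tsv", i)))
  }

  if ("features" %in% stages) {
    p <- need(st$pairs, "pairs", "simulate")
    sch <- need(st$scheme, "binning scheme", "matrix")
    st$coverage <- coverage_track(p, sch)
    st$duplications <- detect_duplications(
      st$coverage, ratio_threshold = config$features$ratio_threshold,
      min_bins = config$features$min_bins)
    write_tsv(st$coverage, file.path(outdir, "coverage.tsv"))
    write_tsv(st$duplications, file.path(outdir, "duplications.tsv"))
  }

  if ("evaluate" %in% stages) {
    tab <- need(st$contig_table, "contig communities", "bin")
    st$report <- eval_report(tab, st$contigs, st$genomes)
    write_eval_report(st$report, file.path(outdir, "eval_report.tsv"))
  }

  manifest <- list(
    seed = seed,
    stages = stages,
    community = lapply(config$community$species, function(sp) list(
      name = sp$name, abundance = sp$abundance,
      replicons = lapply(sp$replicons, function(r)
        list(name = r$name, length = r$length, circular = r$circular)))),
    parameters = config[setdiff(names(config), "community")],
    outputs = as.list(tools::md5sum(
      list.files(outdir, full.names = TRUE, pattern = "\\.(tsv|fasta)$"))))
  names(manifest$outputs) <- basename(names(manifest$outputs))
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  invisible(st)
}
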