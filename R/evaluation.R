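#' Breadth of coverage of the source genomes
#'
#' Fraction of every source genome's length covered by at least one
#' contig, computed from truth intervals as the length of their union
#' (via IRanges) divided by genome length.
#'
#' @param pieces truth intervals (\code{contigs$pieces}): data.frame with
#'   replicon, start, end.
#' @param replicon_lengths named lengths of the genome replicons.
#' @param by \code{"replicon"} or \code{"species"} (needs a species
#'   column and \code{species_lengths} derivable from replicons).
#' @param replicon_species optional named map replicon -> species, needed
#'   for \code{by = "species"}.
#' @return named numeric vector of fractions in [0, 1].
#' @export
breadth_of_coverage <- function(pieces, replicon_lengths,
                                by = c("replicon", "species"),
                                replicon_species = NULL) {
  by <- match.arg(by)
  covered <- vapply(names(replicon_lengths), function(r) {
    pp <- pieces[pieces$replicon == r, , drop = FALSE]
    if (!nrow(pp)) return(0)
    ir <- IRanges::reduce(IRanges::IRanges(start = pp$start + 1L,
                                           end = pp$end))
    sum(IRanges::width(ir))
  }, numeric(1))
  if (by == "replicon") return(covered / unlist(replicon_lengths))
  if (is.null(replicon_species))
    stopf("replicon_species map required for by='species'")
  sp <- replicon_species[names(replicon_lengths)]
  tapply(covered, sp, sum) / tapply(unlist(replicon_lengths), sp, sum)
}

#' Community purity and adjusted Rand index against truth
#'
#' Purity of a community is the fraction of its total contig length
#' contributed by its dominant species. Agreement between the contig ->
#' community and contig -> species maps is summarized by the adjusted
#' Rand index (ARI). Chimeric contigs have no single source species;
#' they are excluded and counted separately.
#'
#' @param contig_table \code{\link{assign_contigs}} result.
#' @param contigs a \code{\link{simulate_contigs}} result (truth).
#' @return list: \code{per_community} (community, dominant_species,
#'   purity, length), \code{ari}, \code{n_chimeric_excluded},
#'   \code{n_unattributed}.
#' @export
community_purity <- function(contig_table, contigs) {
  species_of <- tapply(contigs$pieces$species, contigs$pieces$contig,
                       function(s) if (length(unique(s)) == 1) s[1]
                                   else NA_character_)
  tab <- contig_table
  tab$species <- species_of[tab$contig]
  chim <- is.na(tab$species)
  unatt <- is.na(tab$community)
  use <- tab[!chim & !unatt, , drop = FALSE]
  per <- lapply(split(use, use$community), function(x) {
    w <- tapply(x$length, x$species, sum)
    data.frame(dominant_species = names(w)[which.max(w)],
               purity = max(w) / sum(w), length = sum(w))
  })
  per_comm <- cbind(data.frame(community = as.integer(names(per))),
                    do.call(rbind, per))
  rownames(per_comm) <- NULL
  ari <- mclust::adjustedRandIndex(use$community, use$species)
  list(per_community = per_comm, ari = ari,
       n_chimeric_excluded = sum(chim),
       n_unattributed = sum(unatt & !chim))
}

#' Assembly N50
#'
#' The largest length L such that contigs of length >= L together contain
#' at least half the total assembly length.
#'
#' @param lengths contig lengths.
#' @return N50 in bp.
#' @export
n50 <- function(lengths) {
  if (!length(lengths)) stopf("empty length list")
  s <- sort(lengths, decreasing = TRUE)
  cum <- cumsum(s)
  s[which(cum >= sum(s) / 2)[1]]
}

#' Chimeric-contig rate
#'
#' A contig is chimeric iff its truth intervals span two or more species.
#' Reported both as a fraction of contig count and of total length.
#'
#' @param contigs a \code{\link{simulate_contigs}} result.
#' @return list: \code{n_chimeric}, \code{by_count}, \code{by_length},
#'   \code{chimeric_bp}.
#' @export
chimera_rate <- function(contigs) {
  nsp <- tapply(contigs$pieces$species, contigs$pieces$contig,
                function(s) length(unique(s)))
  chim <- names(nsp)[nsp >= 2]
  ct <- contigs$contigs
  is_chim <- ct$contig %in% chim
  list(n_chimeric = sum(is_chim),
       by_count = mean(is_chim),
       by_length = sum(ct$length[is_chim]) / sum(ct$length),
       chimeric_bp = sum(ct$length[is_chim]))
}

#' Full evaluation report of a synthetic pipeline run
#'
#' Bundles the truth-label scores: per-community purity and dominant
#' species, per-replicon breadth of coverage, chimeric-contig rate, N50
#' and unattributed fractions.
#'
#' @param contig_table \code{\link{assign_contigs}} result.
#' @param contigs \code{\link{simulate_contigs}} result.
#' @param genomes \code{\link{simulate_genomes}} result.
#' @return An \code{eval_report} list; \code{write_eval_report} writes it
#'   as a TSV pair (per-community and global sections).
#' @export
eval_report <- function(contig_table, contigs, genomes) {
  rl <- setNames(genomes$replicons$length, genomes$replicons$replicon)
  pur <- community_purity(contig_table, contigs)
  cov <- breadth_of_coverage(contigs$pieces, rl)
  chim <- chimera_rate(contigs)
  structure(list(
    per_community = pur$per_community,
    ari = pur$ari,
    coverage = cov,
    chimera = chim,
    n50 = n50(contigs$contigs$length),
    n_contigs = nrow(contigs$contigs),
    frac_unattributed = mean(is.na(contig_table$community))),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  cat(sprintf("  contigs: %d (N50 %s bp), chimeric %.3f by count\n",
              x$n_contigs, format(x$n50, big.mark = ","),
              x$chimera$by_count))
  cat(sprintf("  ARI %.3f; unattributed %.3f\n", x$ari,
              x$frac_unattributed))
  for (i in seq_len(nrow(x$per_community)))
    cat(sprintf("  community %d: %s, purity %.3f, %s bp\n",
                x$per_community$community[i],
                x$per_community$dominant_species[i],
                x$per_community$purity[i],
                format(x$per_community$length[i], big.mark = ",")))
  invisible(x)
}

#' @rdname eval_report
#' @param report an \code{eval_report}.
#' @param path output TSV path.
#' @export
write_eval_report <- function(report, path) {
  con <- file(path, "w")
  writeLines("# eval_report", con)
  writeLines(sprintf("#global\tn_contigs\t%d", report$n_contigs), con)
  writeLines(sprintf("#global\tn50\t%d", report$n50), con)
  writeLines(sprintf("#global\tari\t%.6f", report$ari), con)
  writeLines(sprintf("#global\tchimera_by_count\t%.6f",
                     report$chimera$by_count), con)
  writeLines(sprintf("#global\tchimera_by_length\t%.6f",
                     report$chimera$by_length), con)
  writeLines(sprintf("#global\tfrac_unattributed\t%.6f",
                     report$frac_unattributed), con)
  writeLines(sprintf("#coverage\t%s\t%.6f", names(report$coverage),
                     report$coverage), con)
  write.table(report$per_community, con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  close(con)
  invisible(path)
}
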