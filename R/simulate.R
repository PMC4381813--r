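#' Describe a replicon of a simulated species
#'
#' @param name replicon name (unique across the community).
#' @param length replicon length in bp.
#' @param circular is the replicon circular?
#' @export
replicon_config <- function(name, length, circular = FALSE) {
  stopifnot(length >= 1)
  list(name = name, length = as.integer(length), circular = circular)
}

#' Describe a species of a simulated community
#'
#' @param name species name.
#' @param replicons list of \code{\link{replicon_config}} entries
#'   (chromosomes and plasmids alike; a plasmid is simply an extra, usually
#'   circular, replicon of its host species).
#' @param abundance relative cell abundance (> 0).
#' @export
species_config <- function(name, replicons, abundance = 1) {
  stopifnot(abundance > 0, length(replicons) >= 1)
  list(name = name, replicons = replicons, abundance = abundance)
}

#' Configure a synthetic mixed microbial community
#'
#' Defines the genomes the meta3C simulator will emit: a list of species
#' with their replicons and abundances, an optional planted segmental
#' duplication (an interval of one replicon copied into another, e.g. a
#' chromosomal region carried by an F'-like plasmid), and an optional
#' shared-repeat library inserted across species.
#'
#' @param species list of \code{\link{species_config}} entries.
#' @param duplication optional list with fields \code{species},
#'   \code{src_replicon}, \code{src_start}, \code{src_end},
#'   \code{dst_replicon}, \code{dst_start}: the source interval
#'   (0-based half-open) is copied over the destination locus.
#' @param repeats optional list with fields \code{length},
#'   \code{copies_per_species}, \code{species} (names): one repeat sequence
#'   written at random loci of each listed species' first replicon.
#' @return A validated \code{community_config} list.
#' @export
community_config <- function(species, duplication = NULL, repeats = NULL) {
  nm <- vapply(species, `[[`, "", "name")
  if (anyDuplicated(nm)) stopf("species names must be unique")
  rn <- unlist(lapply(species, function(s)
    vapply(s$replicons, `[[`, "", "name")))
  if (anyDuplicated(rn)) stopf("replicon names must be unique")
  if (!is.null(duplication)) {
    d <- duplication
    rln <- unlist(lapply(species, function(s)
      lapply(s$replicons, function(r) r$length)))
    names(rln) <- rn
    seg <- d$src_end - d$src_start
    if (seg <= 0 || seg >= rln[[d$src_replicon]])
      stopf("duplicated segment must be shorter than its source replicon")
    if (d$dst_start + seg > rln[[d$dst_replicon]])
      stopf("duplicated segment does not fit at the insertion target")
  }
  structure(list(species = species, duplication = duplication,
                 repeats = repeats), class = "community_config")
}

random_dna <- function(L) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

#' Simulate the genomes of a community
#'
#' Draws i.i.d.-uniform random DNA for every replicon, then plants the
#' configured duplication (copying the source interval over the target
#' locus, so both copies are exact) and shared repeats. Fully reproducible
#' from the seed. Truth labels record species and coordinates of every
#' planted feature; inference modules never consult them.
#'
#' @param config a \code{\link{community_config}}.
#' @param seed integer seed fixing all draws.
#' @return A \code{meta3c_genomes} object: list with \code{seqs} (named
#'   character), \code{replicons} (data.frame replicon, species, length,
#'   circular, abundance), \code{duplication}, \code{repeats} label tables.
#' @export
simulate_genomes <- function(config, seed) {
  stopifnot(inherits(config, "community_config"))
  with_seed(seed, {
    tabs <- list(); seqs <- character(0)
    for (sp in config$species) {
      for (r in sp$replicons) {
        seqs[[r$name]] <- random_dna(r$length)
        tabs[[length(tabs) + 1L]] <- data.frame(
          replicon = r$name, species = sp$name, length = r$length,
          circular = r$circular, abundance = sp$abundance,
          stringsAsFactors = FALSE)
      }
    }
    replicons <- do.call(rbind, tabs)
    dup_tab <- NULL
    if (!is.null(config$duplication)) {
      d <- config$duplication
      seg <- substr(seqs[[d$src_replicon]], d$src_start + 1L, d$src_end)
      w <- nchar(seg)
      s <- seqs[[d$dst_replicon]]
      seqs[[d$dst_replicon]] <- paste0(
        substr(s, 1L, d$dst_start),
        seg,
        substr(s, d$dst_start + w + 1L, nchar(s)))
      dup_tab <- data.frame(
        species = d$species, src_replicon = d$src_replicon,
        src_start = d$src_start, src_end = d$src_end,
        dst_replicon = d$dst_replicon, dst_start = d$dst_start,
        dst_end = d$dst_start + w, stringsAsFactors = FALSE)
    }
    rep_tab <- NULL
    if (!is.null(config$repeats)) {
      rp <- config$repeats
      rseq <- random_dna(rp$length)
      rows <- list()
      for (spn in rp$species) {
        first_rep <- replicons$replicon[replicons$species == spn][1]
        L <- replicons$length[replicons$replicon == first_rep]
        starts <- sort(sample.int(L - rp$length, rp$copies_per_species))
        # retry until copies do not overlap (cheap at realistic copy counts)
        while (any(diff(starts) < rp$length)) {
          starts <- sort(sample.int(L - rp$length, rp$copies_per_species))
        }
        for (st in starts) {
          s <- seqs[[first_rep]]
          seqs[[first_rep]] <- paste0(
            substr(s, 1L, st), rseq, substr(s, st + rp$length + 1L, nchar(s)))
          rows[[length(rows) + 1L]] <- data.frame(
            species = spn, replicon = first_rep, start = st,
            end = st + rp$length, stringsAsFactors = FALSE)
        }
      }
      rep_tab <- do.call(rbind, rows)
    }
    structure(list(seqs = seqs, replicons = replicons,
                   duplication = dup_tab, repeats = rep_tab),
              class = "meta3c_genomes")
  })
}

#' @export
print.meta3c_genomes <- function(x, ...) {
  cat(sprintf("<meta3c_genomes> %d species, %d replicons, %s bp\n",
              length(unique(x$replicons$species)), nrow(x$replicons),
              format(sum(x$replicons$length), big.mark = ",")))
  invisible(x)
}

#' Simulate an assembly: contigs sliced from the community genomes
#'
#' Replaces a de-novo assembler for testing purposes: contigs are
#' contiguous genome slices whose lengths are drawn to approximate a target
#' N50 (or exactly \code{fixed_length} when given). With probability
#' \code{p_chimeric_join} a contig concatenates slices from two distinct
#' species and is labelled chimeric. Slices tile every replicon exactly, so
#' breadth of coverage of the truth is 1.
#'
#' @param genomes a \code{\link{simulate_genomes}} result.
#' @param target_n50 target contig N50 in bp (>= 1000).
#' @param p_chimeric_join probability a contig is a cross-species join.
#' @param seed integer seed.
#' @param fixed_length optional exact slice length (overrides
#'   \code{target_n50}).
#' @return A \code{meta3c_contigs} object: \code{seqs} (named character),
#'   \code{contigs} (contig, length, chimeric), \code{pieces} (truth
#'   intervals: contig, piece, species, replicon, start, end, contig_start,
#'   contig_end).
#' @export
simulate_contigs <- function(genomes, target_n50 = 20000,
                             p_chimeric_join = 0, seed,
                             fixed_length = NULL) {
  if (is.null(fixed_length) && target_n50 < 1000)
    stopf("target_n50 must be >= 1 kb")
  with_seed(seed, {
    # 1.678: ratio of the length-weighted median to the mean of an
    # exponential, so that exponential slice lengths hit the target N50.
    mean_len <- if (is.null(fixed_length)) target_n50 / 1.678 else NULL
    slices <- list()
    for (i in seq_len(nrow(genomes$replicons))) {
      r <- genomes$replicons[i, ]
      pos <- 0L
      while (pos < r$length) {
        len <- if (!is.null(fixed_length)) fixed_length
               else max(1000L, as.integer(stats::rexp(1, 1 / mean_len)))
        len <- min(len, r$length - pos)
        slices[[length(slices) + 1L]] <- data.frame(
          species = r$species, replicon = r$replicon,
          start = pos, end = pos + len, stringsAsFactors = FALSE)
        pos <- pos + len
      }
    }
    sl <- do.call(rbind, slices)
    queue <- sample.int(nrow(sl))      # random assembly order
    used <- rep(FALSE, nrow(sl))
    contigs <- list(); pieces <- list(); k <- 0L
    for (qi in queue) {
      if (used[qi]) next
      used[qi] <- TRUE
      k <- k + 1L
      id <- sprintf("contig_%05d", k)
      take <- sl[qi, ]
      chim <- FALSE
      if (p_chimeric_join > 0 && runif(1) < p_chimeric_join) {
        cand <- which(!used & sl$species != sl$species[qi])
        if (length(cand)) {
          pj <- if (length(cand) == 1L) cand else sample(cand, 1L)
          used[pj] <- TRUE
          take <- rbind(take, sl[pj, ])
          chim <- TRUE
        }
      }
      lens <- take$end - take$start
      off <- cumsum(c(0L, lens))
      pieces[[k]] <- cbind(
        data.frame(contig = id, piece = seq_len(nrow(take))),
        take,
        data.frame(contig_start = off[-length(off)], contig_end = off[-1]))
      contigs[[k]] <- data.frame(contig = id, length = sum(lens),
                                 chimeric = chim, stringsAsFactors = FALSE)
    }
    pieces <- do.call(rbind, pieces); rownames(pieces) <- NULL
    contigs <- do.call(rbind, contigs)
    seqs <- vapply(split(pieces, pieces$contig), function(pp) {
      pp <- pp[order(pp$piece), ]
      paste(substr(genomes$seqs[pp$replicon], pp$start + 1L, pp$end),
            collapse = "")
    }, character(1))
    structure(list(seqs = seqs[contigs$contig], contigs = contigs,
                   pieces = pieces),
              class = "meta3c_contigs")
  })
}

#' @export
print.meta3c_contigs <- function(x, ...) {
  cat(sprintf("<meta3c_contigs> %d contigs (%d chimeric), N50 %s bp\n",
              nrow(x$contigs), sum(x$contigs$chimeric),
              format(n50(x$contigs$length), big.mark = ",")))
  invisible(x)
}

#' Configure a simulated meta3C pair library
#'
#' The statistical structure of a meta3C library: a fraction
#' \code{p_regular} of ordinary shotgun-like inserts; religation pairs
#' whose genomic separation s follows the polymer-physics contact decay
#' P(s) proportional to s^-alpha (with a resolution floor \code{min_dist});
#' a fraction \code{p_trans_replicon} of religation events joining two
#' replicons of one cell; and a small cross-species chimera fraction
#' \code{p_chimera}.
#'
#' @param n_pairs number of pairs.
#' @param p_regular marginal fraction of regular pairs (default 0.80).
#' @param alpha contact-decay exponent (> 0, default 1.0).
#' @param p_trans_replicon among religation pairs, probability of joining
#'   two replicons of the same cell (default 0.05).
#' @param p_chimera marginal fraction of cross-species pairs
#'   (default 0.0037).
#' @param insert_mean,insert_sd regular-pair insert size (bp).
#' @param read_len read length (bp), used only for orientation bookkeeping.
#' @param min_dist religation separation floor in bp; contacts are not
#'   resolved below roughly one restriction fragment (default 256, the
#'   median fragment length of a 4-base cutter on uniform DNA).
#' @export
library_config <- function(n_pairs, p_regular = 0.80, alpha = 1.0,
                           p_trans_replicon = 0.05, p_chimera = 0.0037,
                           insert_mean = 500, insert_sd = 50,
                           read_len = 65, min_dist = 256) {
  stopifnot(n_pairs >= 1, alpha > 0,
            p_regular >= 0, p_chimera >= 0, p_trans_replicon >= 0,
            p_regular + p_chimera <= 1,
            p_trans_replicon <= 1, min_dist >= 1)
  structure(as.list(environment()), class = "library_config")
}

# Inverse-CDF sampler for a density proportional to s^-alpha on
# [smin, smax].
sample_power <- function(n, alpha, smin, smax) {
  u <- runif(n)
  if (abs(alpha - 1) < 1e-12) {
    s <- smin * (smax / smin)^u
  } else {
    a1 <- 1 - alpha
    s <- (smin^a1 + u * (smax^a1 - smin^a1))^(1 / a1)
  }
  pmax(1, round(s))
}

#' Simulate a meta3C pair library
#'
#' Emits \code{n_pairs} mapped-position pairs over the community genomes.
#' Pair types are drawn from the multinomial (regular, chimera, religation)
#' with the configured marginals; species are chosen proportionally to
#' abundance times genome length, replicons within a species
#' proportionally to length. Regular pairs have normal insert sizes and
#' inward orientation; intra-replicon religation separations follow
#' s^-alpha (circular replicons use circular distance); trans-replicon and
#' cross-species ends are uniform. When the community carries a planted
#' duplication and \code{collapse_duplicates} is TRUE, mapped positions
#' falling inside the second copy are remapped onto the single-copy source
#' interval — emulating alignment of both copies against a one-copy
#' reference, which doubles apparent coverage there. Truth labels
#' (\code{label_*} columns) always record the pre-collapse origin.
#'
#' @param genomes a \code{\link{simulate_genomes}} result.
#' @param lib a \code{\link{library_config}}.
#' @param seed integer seed.
#' @param collapse_duplicates remap the planted duplicate copy onto its
#'   source interval (default TRUE).
#' @return A \code{pair_table}: data.frame with columns ref1, pos1,
#'   strand1, ref2, pos2, strand2, type, and truth columns label_species1,
#'   label_replicon1, label_pos1 (idem 2).
#' @export
simulate_pairs <- function(genomes, lib, seed, collapse_duplicates = TRUE) {
  stopifnot(inherits(lib, "library_config"))
  rt <- genomes$replicons
  n <- lib$n_pairs
  with_seed(seed, {
    sp_names <- unique(rt$species)
    sp_len <- vapply(sp_names, function(s) sum(rt$length[rt$species == s]),
                     numeric(1))
    sp_ab <- vapply(sp_names, function(s) rt$abundance[rt$species == s][1],
                    numeric(1))
    sp_w <- sp_ab * sp_len
    type <- sample(c("regular", "chimera", "religation"), n, replace = TRUE,
                   prob = c(lib$p_regular, lib$p_chimera,
                            1 - lib$p_regular - lib$p_chimera))
    if (lib$p_chimera > 0 && length(sp_names) < 2)
      stopf("chimeric pairs need at least two species")

    pick_replicon <- function(species_vec) {
      # replicon within species, probability proportional to length
      out <- character(length(species_vec))
      for (s in unique(species_vec)) {
        i <- which(species_vec == s)
        reps <- rt[rt$species == s, ]
        out[i] <- if (nrow(reps) == 1L) reps$replicon else
          sample(reps$replicon, length(i), TRUE, prob = reps$length)
      }
      out
    }
    rlen <- setNames(rt$length, rt$replicon)
    rcirc <- setNames(rt$circular, rt$replicon)

    ref1 <- ref2 <- character(n)
    pos1 <- pos2 <- integer(n)
    sp1 <- sp2 <- character(n)
    strand1 <- sample(c("+", "-"), n, TRUE)
    strand2 <- sample(c("+", "-"), n, TRUE)

    ## regular pairs
    ir <- which(type == "regular")
    if (length(ir)) {
      s <- sample(sp_names, length(ir), TRUE, prob = sp_w)
      r <- pick_replicon(s)
      L <- rlen[r]
      ins <- pmax(2L * lib$read_len,
                  round(rnorm(length(ir), lib$insert_mean, lib$insert_sd)))
      ins <- pmin(ins, L - 1L)
      p1 <- floor(runif(length(ir)) * (L - ins))
      ref1[ir] <- r; ref2[ir] <- r
      pos1[ir] <- p1; pos2[ir] <- p1 + ins
      sp1[ir] <- s; sp2[ir] <- s
      strand1[ir] <- "+"; strand2[ir] <- "-"
    }

    ## religation pairs
    il <- which(type == "religation")
    if (length(il)) {
      s <- sample(sp_names, length(il), TRUE, prob = sp_w)
      multi <- vapply(sp_names, function(x) sum(rt$species == x) > 1,
                      logical(1))
      trans <- runif(length(il)) < lib$p_trans_replicon & multi[s]
      # trans-replicon: uniform ends on two distinct replicons of the cell
      it <- which(trans)
      for (j in it) {
        reps <- rt[rt$species == s[j], ]
        two <- sample(nrow(reps), 2L, prob = reps$length)
        k <- il[j]
        ref1[k] <- reps$replicon[two[1]]
        ref2[k] <- reps$replicon[two[2]]
        pos1[k] <- floor(runif(1) * reps$length[two[1]])
        pos2[k] <- floor(runif(1) * reps$length[two[2]])
      }
      # intra-replicon: separation from the power-law decay
      ii <- il[!trans]
      if (length(ii)) {
        r <- pick_replicon(s[!trans])
        L <- rlen[r]
        smax <- ifelse(rcirc[r], pmax(lib$min_dist + 1, floor(L / 2)),
                       pmax(lib$min_dist + 1, L - 1))
        sdist <- sample_power(length(ii), lib$alpha, lib$min_dist, smax)
        sgn <- sample(c(-1L, 1L), length(ii), TRUE)
        p1 <- floor(runif(length(ii)) * L)
        p2 <- p1 + sgn * sdist
        circ <- rcirc[r]
        p2[circ] <- p2[circ] %% L[circ]
        # linear replicons: reflect runs off the ends back inside
        bad <- !circ & (p2 < 0 | p2 >= L)
        p2[bad] <- p1[bad] - (sgn[bad] * sdist[bad])
        bad2 <- !circ & (p2 < 0 | p2 >= L)
        p2[bad2] <- pmin(pmax(p2[bad2], 0), L[bad2] - 1)
        ref1[ii] <- r; ref2[ii] <- r
        pos1[ii] <- p1; pos2[ii] <- as.integer(p2)
        sp1[ii] <- r_species <- rt$species[match(r, rt$replicon)]
        sp2[ii] <- r_species
      }
      sp1[il[trans]] <- s[trans]; sp2[il[trans]] <- s[trans]
    }

    ## chimeric (cross-species) pairs
    ic <- which(type == "chimera")
    if (length(ic)) {
      sA <- sample(sp_names, length(ic), TRUE, prob = sp_w)
      sB <- character(length(ic))
      for (s in unique(sA)) {
        j <- which(sA == s)
        others <- setdiff(sp_names, s)
        w <- sp_w[others]
        sB[j] <- if (length(others) == 1L) others else
          sample(others, length(j), TRUE, prob = w)
      }
      rA <- pick_replicon(sA); rB <- pick_replicon(sB)
      ref1[ic] <- rA; ref2[ic] <- rB
      pos1[ic] <- floor(runif(length(ic)) * rlen[rA])
      pos2[ic] <- floor(runif(length(ic)) * rlen[rB])
      sp1[ic] <- sA; sp2[ic] <- sB
    }

    pairs <- data.frame(
      ref1 = ref1, pos1 = pos1, strand1 = strand1,
      ref2 = ref2, pos2 = pos2, strand2 = strand2,
      type = type,
      label_species1 = sp1, label_replicon1 = ref1, label_pos1 = pos1,
      label_species2 = sp2, label_replicon2 = ref2, label_pos2 = pos2,
      stringsAsFactors = FALSE)

    if (collapse_duplicates && !is.null(genomes$duplication)) {
      d <- genomes$duplication
      for (side in 1:2) {
        refc <- paste0("ref", side); posc <- paste0("pos", side)
        hit <- pairs[[refc]] == d$dst_replicon &
               pairs[[posc]] >= d$dst_start & pairs[[posc]] < d$dst_end
        pairs[[posc]][hit] <- d$src_start +
          (pairs[[posc]][hit] - d$dst_start)
        pairs[[refc]][hit] <- d$src_replicon
      }
    }
    class(pairs) <- c("pair_table", "data.frame")
    pairs
  })
}

#' Re-map genome-coordinate pairs onto contig coordinates
#'
#' Emulates aligning the library against the simulated assembly: every
#' pair end is translated to (contig, position) through the contigs' truth
#' intervals, which tile the genomes. Ends are preserved; truth label
#' columns are carried through.
#'
#' @param pairs a \code{pair_table} in genome coordinates.
#' @param contigs a \code{\link{simulate_contigs}} result.
#' @return A \code{pair_table} with contig names in ref1/ref2.
#' @export
map_pairs_to_contigs <- function(pairs, contigs) {
  pc <- contigs$pieces
  out <- pairs
  for (side in 1:2) {
    refc <- paste0("ref", side); posc <- paste0("pos", side)
    ref <- out[[refc]]; pos <- out[[posc]]
    new_ref <- character(length(ref)); new_pos <- integer(length(ref))
    for (r in unique(ref)) {
      i <- which(ref == r)
      pp <- pc[pc$replicon == r, ]
      pp <- pp[order(pp$start), ]
      j <- findInterval(pos[i], pp$start)
      new_ref[i] <- pp$contig[j]
      new_pos[i] <- pp$contig_start[j] + (pos[i] - pp$start[j])
    }
    out[[refc]] <- new_ref; out[[posc]] <- new_pos
  }
  out
}

#' Write / read a pair table as TSV
#'
#' Columns: readID, ref1, pos1, strand1, ref2, pos2, strand2 plus any
#' label columns present.
#' @param pairs pair table.
#' @param path file path.
#' @export
write_pairs <- function(pairs, path) {
  out <- cbind(readID = sprintf("pair_%07d", seq_len(nrow(pairs))), pairs)
  write_tsv(out, path)
}

#' @rdname write_pairs
#' @export
read_pairs <- function(path) {
  x <- read_tsv(path)
  x$readID <- NULL
  class(x) <- c("pair_table", "data.frame")
  x
}
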