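#' Define a restriction enzyme
#'
#' A restriction enzyme is described by its recognition site and the offset
#' of the cut within that site. All coordinates in this package are 0-based,
#' half-open. Site matching is performed on the given strand only; the
#' enzymes commonly used in 3C protocols (HpaII \code{C^CGG}, DpnII
#' \code{^GATC}, HaeIII \code{GG^CC}) have palindromic sites so this is
#' strand-symmetric. Overlapping site occurrences are all cut, and \code{N}
#' bases never match.
#'
#' @param name enzyme name.
#' @param site recognition site, a DNA string over \code{A,C,G,T}.
#' @param cut_offset 0-based offset of the cut within the site
#'   (\code{0 <= cut_offset <= nchar(site)}).
#' @return An object of class \code{"enzyme"}.
#' @examples
#' enzyme("HpaII", "CCGG", 1)
#' @export
enzyme <- function(name, site, cut_offset) {
  site <- toupper(site)
  if (!nzchar(site) || grepl("[^ACGT]", site))
    stopf("enzyme site must be a non-empty string over A,C,G,T: %s", site)
  cut_offset <- as.integer(cut_offset)
  if (cut_offset < 0L || cut_offset > nchar(site))
    stopf("cut_offset must lie within the site (0..%d)", nchar(site))
  structure(list(name = name, site = site, cut_offset = cut_offset),
            class = "enzyme")
}

#' Common 3C restriction enzymes
#'
#' @param name one of \code{"HpaII"}, \code{"DpnII"}, \code{"HaeIII"}.
#' @return An \code{\link{enzyme}} object.
#' @export
known_enzyme <- function(name) {
  presets <- list(
    HpaII  = c("CCGG", 1L),   # C^CGG
    DpnII  = c("GATC", 0L),   # ^GATC
    HaeIII = c("GGCC", 2L)    # GG^CC
  )
  if (!name %in% names(presets)) stopf("unknown enzyme: %s", name)
  p <- presets[[name]]
  enzyme(name, p[1], as.integer(p[2]))
}

#' @export
print.enzyme <- function(x, ...) {
  cat(sprintf("<enzyme> %s %s^%s\n", x$name,
              substr(x$site, 1, x$cut_offset),
              substr(x$site, x$cut_offset + 1, nchar(x$site))))
  invisible(x)
}

# All 0-based cut positions of `enz` on one sequence.
# For circular sequences, occurrences wrapping the origin are included and
# cut positions are taken modulo L.
cut_positions <- function(seq, enz, circular) {
  seq <- as.character(seq)
  L <- nchar(seq)
  w <- nchar(enz$site)
  if (w > L && !circular) return(integer(0))
  subject <- if (circular && w > 1) paste0(seq, substr(seq, 1, w - 1)) else seq
  hits <- Biostrings::matchPattern(enz$site,
                                   Biostrings::DNAString(subject),
                                   fixed = TRUE)
  starts0 <- Biostrings::start(hits) - 1L   # 0-based occurrence starts
  starts0 <- starts0[starts0 < L]           # wrap copies start beyond L-1
  cuts <- starts0 + enz$cut_offset
  if (circular) cuts <- cuts %% L else cuts <- cuts[cuts > 0L & cuts < L]
  sort(unique(as.integer(cuts)))
}

#' In-silico restriction digestion of one replicon
#'
#' Cuts a replicon at every occurrence of the enzyme site (overlaps
#' included) and returns the ordered restriction fragments as 0-based,
#' half-open intervals. On a circular replicon, site occurrences spanning
#' the origin are detected; with at least one cut, the fragment spanning the
#' origin wraps (its \code{end} exceeds the replicon length and
#' \code{wraps} is \code{TRUE}). A sequence with no site occurrence yields a
#' single full-length fragment.
#'
#' @param seq DNA sequence (character or \code{DNAString}).
#' @param enz an \code{\link{enzyme}}.
#' @param circular is the replicon circular?
#' @return data.frame with columns \code{start}, \code{end}, \code{length},
#'   \code{wraps}.
#' @examples
#' digest("AACCGGT", known_enzyme("HpaII"))        # fragments [0,3) [3,7)
#' digest("AAGGCCTT", known_enzyme("HaeIII"), circular = TRUE)
#' @export
digest <- function(seq, enz, circular = FALSE) {
  seq <- as.character(seq)
  L <- nchar(seq)
  if (L < 1L) stopf("replicon sequence is empty")
  cuts <- cut_positions(seq, enz, circular)
  if (length(cuts) == 0L) {
    return(data.frame(start = 0L, end = L, length = L, wraps = FALSE))
  }
  if (!circular) {
    bounds <- unique(c(0L, cuts, L))
    st <- bounds[-length(bounds)]
    en <- bounds[-1]
    return(data.frame(start = st, end = en, length = en - st, wraps = FALSE))
  }
  # circular: fragments run cut_i -> cut_{i+1}; the last wraps to cut_1 + L
  k <- length(cuts)
  st <- cuts
  en <- c(cuts[-1], cuts[1] + L)
  data.frame(start = st, end = en, length = en - st, wraps = en > L)
}

#' Digest a set of replicons into a fragment map
#'
#' Applies \code{\link{digest}} to every replicon of a genome set and
#' assembles the coordinate system all contacts are assigned to: an ordered
#' table of restriction fragments with contiguous global indices following
#' replicon order. Fragments tile each replicon exactly.
#'
#' @param genomes named character vector or \code{DNAStringSet}; names are
#'   replicon names (unique).
#' @param enz an \code{\link{enzyme}}.
#' @param circular logical, recycled over replicons (or named logical).
#' @return A \code{fragment_map}: data.frame with columns \code{replicon},
#'   \code{frag} (global 1-based index), \code{start}, \code{end},
#'   \code{length}, \code{wraps}; attributes \code{replicon_lengths} and
#'   \code{circular}.
#' @export
digest_genomes <- function(genomes, enz, circular = FALSE) {
  nm <- names(genomes)
  seqs <- setNames(as.character(genomes), nm)
  if (is.null(nm) || anyDuplicated(nm))
    stopf("replicon names must be present and unique")
  circ <- if (!is.null(names(circular))) {
    unname(circular[nm])
  } else rep_len(circular, length(seqs))
  parts <- lapply(seq_along(seqs), function(i) {
    f <- digest(seqs[[i]], enz, circ[i])
    cbind(data.frame(replicon = nm[i], stringsAsFactors = FALSE), f)
  })
  fm <- do.call(rbind, parts)
  fm <- cbind(fm[, "replicon", drop = FALSE], frag = seq_len(nrow(fm)),
              fm[, c("start", "end", "length", "wraps")])
  rownames(fm) <- NULL
  structure(fm,
            replicon_lengths = setNames(nchar(seqs), nm),
            circular = setNames(as.logical(circ), nm),
            class = c("fragment_map", "data.frame"))
}

#' @export
print.fragment_map <- function(x, ...) {
  rl <- attr(x, "replicon_lengths")
  cat(sprintf("<fragment_map> %d fragments over %d replicon(s), %s bp total\n",
              nrow(x), length(rl), format(sum(rl), big.mark = ",")))
  invisible(x)
}

#' Locate the fragment containing a genomic position
#'
#' Vectorised lookup of the unique restriction fragment containing each
#' (replicon, position) under the 0-based half-open convention. Positions
#' inside the origin-spanning fragment of a circular replicon are resolved
#' by a modular interval test.
#'
#' @param fmap a \code{\link{digest_genomes}} fragment map.
#' @param replicon character vector of replicon names.
#' @param position integer vector of 0-based positions.
#' @return integer vector of global fragment indices.
#' @export
locate_fragment <- function(fmap, replicon, position) {
  rl <- attr(fmap, "replicon_lengths")
  unknown <- setdiff(unique(replicon), names(rl))
  if (length(unknown)) stopf("unknown replicon: %s", unknown[1])
  out <- integer(length(position))
  for (r in unique(replicon)) {
    idx <- which(replicon == r)
    L <- rl[[r]]
    p <- position[idx]
    if (any(p < 0L | p >= L)) stopf("position out of range on %s", r)
    sub <- fmap[fmap$replicon == r, ]
    wrap_row <- which(sub$wraps)
    res <- integer(length(p))
    if (length(wrap_row)) {
      ws <- sub$start[wrap_row]; we <- sub$end[wrap_row] - L
      inw <- p >= ws | p < we
      res[inw] <- sub$frag[wrap_row]
      rest <- !inw
    } else rest <- rep(TRUE, length(p))
    if (any(rest)) {
      lin <- sub[!sub$wraps, ]
      res[rest] <- lin$frag[findInterval(p[rest], lin$start)]
    }
    out[idx] <- res
  }
  out
}

#' Build a binning scheme over a fragment map
#'
#' Groups restriction fragments into bins, either as runs of a fixed number
#' of consecutive fragments (\code{mode = "fragments"}, the classic
#' 10- or 200-fragment units) or by fixed genomic width in bp
#' (\code{mode = "basepairs"}, e.g. 30 kb bins). Bins never span replicons;
#' the last bin of a replicon may be smaller.
#'
#' @param fmap a \code{\link{digest_genomes}} fragment map.
#' @param width bin width: number of fragments, or bp.
#' @param mode \code{"fragments"} or \code{"basepairs"}.
#' @return A \code{binning_scheme}: list with \code{bins} (data.frame
#'   \code{bin}, \code{replicon}, \code{start}, \code{end}, \code{n_frags}),
#'   \code{frag2bin} (global fragment index -> bin), \code{mode},
#'   \code{width}.
#' @export
make_bins <- function(fmap, width, mode = c("fragments", "basepairs")) {
  mode <- match.arg(mode)
  width <- as.integer(width)
  if (width < 1L) stopf("bin width must be >= 1")
  rl <- attr(fmap, "replicon_lengths")
  frag2bin <- integer(nrow(fmap))
  rows <- list()
  offset <- 0L
  for (r in names(rl)) {
    sel <- fmap$replicon == r
    sub <- fmap[sel, ]
    if (mode == "fragments") {
      local_bin <- (seq_len(nrow(sub)) - 1L) %/% width + 1L
    } else {
      local_bin <- as.integer(sub$start %/% width) + 1L
      local_bin <- match(local_bin, sort(unique(local_bin)))
    }
    frag2bin[sub$frag] <- offset + local_bin
    agg_start <- tapply(sub$start, local_bin, min)
    agg_end <- tapply(sub$end, local_bin, max)
    agg_n <- tapply(sub$start, local_bin, length)
    rows[[r]] <- data.frame(
      bin = offset + sort(unique(local_bin)),
      replicon = r,
      start = as.integer(agg_start), end = as.integer(agg_end),
      n_frags = as.integer(agg_n), stringsAsFactors = FALSE)
    offset <- offset + max(local_bin)
  }
  bins <- do.call(rbind, rows)
  rownames(bins) <- NULL
  structure(list(bins = bins, frag2bin = frag2bin, mode = mode,
                 width = width, fmap = fmap),
            class = "binning_scheme")
}

#' @export
print.binning_scheme <- function(x, ...) {
  cat(sprintf("<binning_scheme> %d bins (%s, width %d)\n",
              nrow(x$bins), x$mode, x$width))
  invisible(x)
}

# Map (replicon, position) vectors to bin indices under a scheme.
position_to_bin <- function(scheme, replicon, position) {
  scheme$frag2bin[locate_fragment(scheme$fmap, replicon, position)]
}

#' Read / write FASTA
#'
#' Thin wrappers around Biostrings multi-record FASTA I/O; record ids are
#' replicon or contig names. Circularity is carried separately in configs,
#' never encoded in headers.
#'
#' @param path file path.
#' @return \code{read_fasta}: a named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' @param seqs named character vector of sequences.
#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs), path, width = 80L)
  invisible(path)
}

#' Export a fragment map as TSV
#'
#' Columns: replicon, frag_index, start, end, length.
#' @param fmap fragment map.
#' @param path output path.
#' @export
write_fragment_map <- function(fmap, path) {
  out <- data.frame(replicon = fmap$replicon, frag_index = fmap$frag,
                    start = fmap$start, end = fmap$end,
                    length = fmap$length)
  write_tsv(out, path)
}
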