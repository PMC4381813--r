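#' Fixed-width bins without a fragment map
#'
#' A basepair binning scheme defined directly on replicon lengths:
#' positions map to bins of \code{width} bp, bins never span replicons.
#' Useful when contacts are analysed at a genomic scale coarser than
#' restriction fragments (e.g. 10-30 kb bins).
#'
#' @param replicon_lengths named integer vector.
#' @param width bin width in bp.
#' @return A \code{binning_scheme} with \code{fmap = NULL}.
#' @export
bp_bins <- function(replicon_lengths, width) {
  width <- as.integer(width)
  if (width < 1L) stopf("bin width must be >= 1")
  rows <- list(); offset <- 0L
  for (r in names(replicon_lengths)) {
    L <- replicon_lengths[[r]]
    nb <- as.integer(ceiling(L / width))
    st <- (seq_len(nb) - 1L) * width
    rows[[r]] <- data.frame(bin = offset + seq_len(nb), replicon = r,
                            start = st, end = pmin(st + width, L),
                            n_frags = NA_integer_, stringsAsFactors = FALSE)
    offset <- offset + nb
  }
  bins <- do.call(rbind, rows); rownames(bins) <- NULL
  structure(list(bins = bins, frag2bin = NULL, mode = "basepairs",
                 width = width, fmap = NULL,
                 replicon_lengths = replicon_lengths),
            class = "binning_scheme")
}

# (replicon, position) -> bin index for either kind of scheme.
scheme_bin <- function(scheme, replicon, position) {
  if (!is.null(scheme$fmap))
    return(position_to_bin(scheme, replicon, position))
  b <- scheme$bins
  out <- integer(length(position))
  for (r in unique(replicon)) {
    i <- which(replicon == r)
    sub <- b[b$replicon == r, ]
    if (!nrow(sub)) { out[i] <- NA_integer_; next }
    loc <- position[i] %/% scheme$width + 1L
    loc[loc > nrow(sub)] <- nrow(sub)
    out[i] <- sub$bin[1] - 1L + loc
  }
  out
}

#' Collapse PCR duplicates in a pair table
#'
#' Ends are first put in canonical order (an unordered pair (i,j) equals
#' (j,i)), then rows identical on (ref1, pos1, strand1, ref2, pos2,
#' strand2) are collapsed to one. The number of removed rows is attached
#' as attribute \code{"removed"}.
#'
#' @param pairs a \code{pair_table}.
#' @return Deduplicated \code{pair_table}.
#' @export
dedup_pairs <- function(pairs) {
  sw <- pairs$ref2 < pairs$ref1 |
    (pairs$ref2 == pairs$ref1 & pairs$pos2 < pairs$pos1)
  canon <- pairs
  for (col in c("ref", "pos", "strand")) {
    a <- paste0(col, "1"); b <- paste0(col, "2")
    tmp <- canon[[a]][sw]
    canon[[a]][sw] <- canon[[b]][sw]
    canon[[b]][sw] <- tmp
  }
  lab <- grep("^label_", names(canon), value = TRUE)
  if (length(lab)) {
    for (col in c("species", "replicon", "pos")) {
      a <- paste0("label_", col, "1"); b <- paste0("label_", col, "2")
      if (all(c(a, b) %in% names(canon))) {
        tmp <- canon[[a]][sw]
        canon[[a]][sw] <- canon[[b]][sw]
        canon[[b]][sw] <- tmp
      }
    }
  }
  key <- paste(canon$ref1, canon$pos1, canon$strand1,
               canon$ref2, canon$pos2, canon$strand2, sep = "\r")
  keep <- !duplicated(key)
  out <- canon[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pair_table", "data.frame")
  attr(out, "removed") <- sum(!keep)
  out
}

#' Build a raw contact matrix from a pair table
#'
#' Each accepted pair increments the symmetric count between the bins of
#' its two ends (self-bin pairs go on the diagonal; each pair is counted
#' once, both triangles populated by symmetry). Pairs referencing a
#' replicon unknown to the scheme are rejected and counted in attribute
#' \code{"rejected"}.
#'
#' @param pairs a \code{pair_table}.
#' @param scheme a \code{binning_scheme} (\code{\link{make_bins}} or
#'   \code{\link{bp_bins}}).
#' @return A \code{contact_matrix} with state \code{"raw"}.
#' @export
build_matrix <- function(pairs, scheme) {
  b <- scheme$bins
  known <- unique(b$replicon)
  ok <- pairs$ref1 %in% known & pairs$ref2 %in% known
  rejected <- sum(!ok)
  p <- pairs[ok, , drop = FALSE]
  n <- nrow(b)
  i <- scheme_bin(scheme, p$ref1, p$pos1)
  j <- scheme_bin(scheme, p$ref2, p$pos2)
  lo <- pmin(i, j); hi <- pmax(i, j)
  if (n <= 3000) {
    counts <- tabulate((lo - 1L) * n + hi, nbins = n * n)
    m <- matrix(counts, n, n, byrow = TRUE)
  } else {
    key <- (as.numeric(lo) - 1) * n + hi
    tab <- table(key)
    k <- as.numeric(names(tab))
    m <- matrix(0, n, n)
    m[cbind(floor((k - 1) / n) + 1, ((k - 1) %% n) + 1)] <- as.numeric(tab)
  }
  m <- m + t(m) - diag(diag(m))
  contact_matrix(m, b, state = "raw", rejected = rejected)
}

#' Construct a contact matrix container
#'
#' Wraps a symmetric numeric matrix with its bin labels and normalization
#' state. \code{\link{build_matrix}} is the usual entry point; this
#' constructor serves matrices produced elsewhere. When \code{bins} is
#' omitted, unit-width bins on a single replicon are generated.
#'
#' @param m square numeric matrix.
#' @param bins data.frame with columns bin, replicon, start, end.
#' @param state one of \code{"raw"}, \code{"scn"}, \code{"pearson"}.
#' @param ... further metadata stored in \code{$meta}.
#' @export
contact_matrix <- function(m, bins = NULL, state = "raw", ...) {
  if (is.null(bins)) {
    n <- nrow(m)
    bins <- data.frame(bin = seq_len(n), replicon = "r",
                       start = seq_len(n) - 1L, end = seq_len(n),
                       stringsAsFactors = FALSE)
  }
  stopifnot(nrow(m) == ncol(m), nrow(m) == nrow(bins))
  dimnames(m) <- NULL
  structure(list(m = m, bins = bins, state = state, meta = list(...)),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("<contact_matrix> %d x %d bins, state=%s, mass=%.4g\n",
              nrow(x$m), ncol(x$m), x$state,
              sum(x$m[upper.tri(x$m, diag = TRUE)])))
  invisible(x)
}

#' @export
dim.contact_matrix <- function(x) dim(x$m)

#' Sequential component normalization (SCN)
#'
#' Iteratively divides every column of the contact matrix by its sum and
#' then every row by its sum, until the largest deviation of any row or
#' column sum from 1 falls below \code{tol}. Empty bins (all-zero rows)
#' are dropped beforehand and reported in \code{meta$dropped_bins}; after
#' convergence symmetry is restored by averaging with the transpose. The
#' result has every non-empty row and column summing to 1 within
#' tolerance, which removes the per-bin coverage biases of the protocol.
#'
#' @param cm a raw \code{contact_matrix}.
#' @param tol convergence tolerance on max |sum - 1| (default 1e-6).
#' @param max_iter maximum number of column+row sweeps (default 100).
#' @return A \code{contact_matrix} with state \code{"scn"};
#'   \code{meta$iterations}, \code{meta$achieved} (final deviation) and
#'   \code{meta$converged} record the run.
#' @export
scn_normalize <- function(cm, tol = 1e-6, max_iter = 100) {
  stopifnot(inherits(cm, "contact_matrix"))
  m <- cm$m
  keep <- rowSums(m) > 0
  if (!any(keep)) stopf("all-zero contact matrix cannot be normalized")
  dropped <- cm$bins$bin[!keep]
  m <- m[keep, keep, drop = FALSE]
  bins <- cm$bins[keep, , drop = FALSE]
  achieved <- Inf; it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    cs <- colSums(m)
    m <- sweep(m, 2, ifelse(cs > 0, cs, 1), "/")
    rs <- rowSums(m)
    m <- m / ifelse(rs > 0, rs, 1)
    achieved <- max(abs(c(rowSums(m), colSums(m)) - 1))
    if (achieved < tol) break
  }
  converged <- achieved < tol
  if (!converged)
    warning(sprintf("SCN did not converge in %d iterations (dev %.3g)",
                    max_iter, achieved))
  m <- (m + t(m)) / 2
  contact_matrix(m, bins, state = "scn", dropped_bins = dropped,
                 iterations = it, achieved = achieved,
                 converged = converged)
}

#' Pearson correlation map of an SCN matrix
#'
#' Entry (i, j) is the Pearson correlation between rows i and j of the
#' normalized matrix; the diagonal is 1 and values lie in [-1, 1]. With
#' \code{exclude_diag = TRUE} the self entries of the two rows are left
#' out of each correlation. Constant rows have undefined correlations;
#' these entries are set to 0 and the bins listed in
#' \code{meta$flagged_bins}.
#'
#' @param cm a \code{contact_matrix} with state \code{"scn"}.
#' @param exclude_diag drop the two self entries from each correlation.
#' @return A \code{contact_matrix} with state \code{"pearson"}.
#' @export
pearson_map <- function(cm, exclude_diag = FALSE) {
  if (cm$state != "scn") stopf("pearson_map expects an SCN matrix")
  m <- cm$m
  if (exclude_diag) {
    diag(m) <- NA
    C <- suppressWarnings(cor(t(m), use = "pairwise.complete.obs"))
  } else {
    C <- suppressWarnings(cor(t(m)))
  }
  flagged <- which(apply(cm$m, 1, function(r) stats::sd(r) == 0))
  C[!is.finite(C)] <- 0
  diag(C) <- 1
  contact_matrix(C, cm$bins, state = "pearson",
                 flagged_bins = cm$bins$bin[flagged])
}

#' Remove genomic regions from a contact matrix
#'
#' Rows and columns of every bin overlapping any region are removed and
#' the matrix shrinks; surviving bins keep their labels. Used e.g. to
#' exclude a segmental duplication from downstream analyses.
#'
#' @param cm a \code{contact_matrix}.
#' @param regions data.frame with columns replicon, start, end (0-based
#'   half-open).
#' @return The reduced \code{contact_matrix} (same state).
#' @export
mask_regions <- function(cm, regions) {
  if (is.null(regions) || nrow(regions) == 0) return(cm)
  b <- cm$bins
  if (any(!regions$replicon %in% b$replicon))
    stopf("mask region on unknown replicon")
  drop <- rep(FALSE, nrow(b))
  for (k in seq_len(nrow(regions))) {
    rg <- regions[k, ]
    drop <- drop | (b$replicon == rg$replicon &
                      b$start < rg$end & b$end > rg$start)
  }
  keep <- !drop
  do.call(contact_matrix,
          c(list(cm$m[keep, keep, drop = FALSE],
                 b[keep, , drop = FALSE], state = cm$state),
            cm$meta))
}

#' Fraction of cross-species pairs
#'
#' The interspecies background of a labelled library: the fraction of
#' pairs whose two ends carry different species truth labels.
#'
#' @param pairs a labelled \code{pair_table}.
#' @return A single fraction in [0, 1].
#' @export
interspecies_fraction <- function(pairs) {
  if (!all(c("label_species1", "label_species2") %in% names(pairs)))
    stopf("pair table carries no species labels")
  mean(pairs$label_species1 != pairs$label_species2)
}

#' Contact distance-decay curve and exponent fit
#'
#' Computes the intra-replicon contact frequency as a function of genomic
#' separation (circular replicons use circular distance) on
#' logarithmically spaced distance bins, and fits the decay exponent
#' alpha of P(s) ~ s^-alpha by linear regression of log frequency on log
#' distance.
#'
#' @param pairs a \code{pair_table} (genome coordinates).
#' @param replicon_lengths named lengths of the replicons to use.
#' @param circular named logical (or single value) per replicon.
#' @param dmin,dmax distance range for the fit (bp).
#' @param nbins number of log-spaced distance bins.
#' @return data.frame (dist, freq) with attribute \code{"alpha"} (fitted
#'   exponent) and \code{"slope"}.
#' @export
distance_decay <- function(pairs, replicon_lengths, circular = FALSE,
                           dmin = 1000, dmax = NULL, nbins = 25) {
  circ <- if (!is.null(names(circular))) circular else
    setNames(rep_len(circular, length(replicon_lengths)),
             names(replicon_lengths))
  keep <- pairs$ref1 == pairs$ref2 & pairs$ref1 %in% names(replicon_lengths)
  p <- pairs[keep, ]
  d <- abs(p$pos2 - p$pos1)
  L <- replicon_lengths[p$ref1]
  iscirc <- circ[p$ref1]
  d[iscirc] <- pmin(d[iscirc], L[iscirc] - d[iscirc])
  if (is.null(dmax)) dmax <- max(replicon_lengths) / 2
  d <- d[d >= dmin & d <= dmax]
  if (length(d) < 100) stopf("too few intra-replicon pairs for a decay fit")
  edges <- exp(seq(log(dmin), log(dmax), length.out = nbins + 1))
  h <- hist(d, breaks = edges, plot = FALSE)
  mid <- sqrt(edges[-1] * edges[-length(edges)])
  freq <- h$counts / diff(edges)        # density per bp of separation
  ok <- freq > 0
  fit <- stats::lm(log(freq[ok]) ~ log(mid[ok]))
  out <- data.frame(dist = mid, freq = freq)
  attr(out, "slope") <- unname(stats::coef(fit)[2])
  attr(out, "alpha") <- -unname(stats::coef(fit)[2])
  out
}

#' Contact matrix I/O
#'
#' \code{write_contact_matrix} writes a dense TSV whose first three
#' columns are the bin labels (replicon, start, end) followed by one
#' column per bin; \code{write_contact_matrix_coo} writes a sparse
#' COO TSV (bin1, bin2, value, upper triangle incl. diagonal) preceded by
#' commented bin-label lines. Both round-trip losslessly through the
#' matching readers.
#'
#' @param cm contact matrix.
#' @param path file path.
#' @name contact_matrix_io
#' @export
write_contact_matrix <- function(cm, path) {
  vals <- as.data.frame(apply(cm$m, 2, function(x) sprintf("%.17g", x)))
  df <- cbind(cm$bins[, c("replicon", "start", "end")], vals)
  names(df) <- c("replicon", "start", "end",
                 paste0("b", cm$bins$bin))
  con <- file(path, "w")
  writeLines(sprintf("# contact_matrix state=%s", cm$state), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname contact_matrix_io
#' @export
read_contact_matrix <- function(path) {
  header <- readLines(path, n = 1)
  state <- sub("^# contact_matrix state=", "", header)
  df <- read_tsv(path, comment.char = "#")
  bins <- data.frame(
    bin = as.integer(sub("^b", "", names(df)[-(1:3)])),
    replicon = df$replicon, start = df$start, end = df$end,
    stringsAsFactors = FALSE)
  m <- as.matrix(df[, -(1:3), drop = FALSE])
  contact_matrix(unname(m), bins, state = state)
}

#' @rdname contact_matrix_io
#' @export
write_contact_matrix_coo <- function(cm, path) {
  con <- file(path, "w")
  writeLines(sprintf("# contact_matrix state=%s", cm$state), con)
  writeLines(sprintf("#bin\t%d\t%s\t%d\t%d", cm$bins$bin,
                     cm$bins$replicon, cm$bins$start, cm$bins$end), con)
  idx <- which(upper.tri(cm$m, diag = TRUE) & cm$m != 0, arr.ind = TRUE)
  df <- data.frame(bin1 = cm$bins$bin[idx[, 1]],
                   bin2 = cm$bins$bin[idx[, 2]],
                   value = cm$m[idx])
  df <- df[order(df$bin1, df$bin2), ]
  df$value <- sprintf("%.17g", df$value)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname contact_matrix_io
#' @export
read_contact_matrix_coo <- function(path) {
  lines <- readLines(path)
  state <- sub("^# contact_matrix state=", "", lines[1])
  binl <- grep("^#bin\t", lines, value = TRUE)
  parts <- strsplit(sub("^#bin\t", "", binl), "\t")
  bins <- data.frame(
    bin = as.integer(vapply(parts, `[`, "", 1)),
    replicon = vapply(parts, `[`, "", 2),
    start = as.integer(vapply(parts, `[`, "", 3)),
    end = as.integer(vapply(parts, `[`, "", 4)),
    stringsAsFactors = FALSE)
  df <- read_tsv(path, comment.char = "#")
  n <- nrow(bins)
  m <- matrix(0, n, n)
  i <- match(df$bin1, bins$bin); j <- match(df$bin2, bins$bin)
  m[cbind(i, j)] <- df$value
  m[cbind(j, i)] <- df$value
  contact_matrix(m, bins, state = state)
}
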