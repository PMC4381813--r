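#' Per-bin coverage track from a pair table
#'
#' Every pair end increments its bin's count; counts are then normalized
#' by the genome-wide median over non-empty bins, so ordinary single-copy
#' regions sit at 1 and a collapsed segmental duplication at about 2.
#'
#' @param pairs a \code{pair_table} in genome coordinates.
#' @param scheme a \code{binning_scheme}.
#' @return A \code{coverage_track}: data.frame (bin, replicon, start,
#'   end, count, coverage) where \code{coverage} is median-normalized.
#' @export
coverage_track <- function(pairs, scheme) {
  if (nrow(pairs) == 0) stopf("no pairs")
  b <- scheme$bins
  known <- unique(b$replicon)
  ok1 <- pairs$ref1 %in% known; ok2 <- pairs$ref2 %in% known
  i <- scheme_bin(scheme, pairs$ref1[ok1], pairs$pos1[ok1])
  j <- scheme_bin(scheme, pairs$ref2[ok2], pairs$pos2[ok2])
  counts <- tabulate(c(i, j), nbins = nrow(b))
  med <- median(counts[counts > 0])
  out <- cbind(b[, c("bin", "replicon", "start", "end")],
               count = counts, coverage = counts / med)
  structure(out, class = c("coverage_track", "data.frame"))
}

#' Detect segmental duplications from a coverage track
#'
#' Scans each replicon for maximal runs of at least \code{min_bins}
#' consecutive bins whose normalized coverage is at or above
#' \code{ratio_threshold}; each run is reported with its mean coverage
#' ratio. The default threshold 1.6 sits between single copy (1) and a
#' clean two-copy duplication (2).
#'
#' @param cov a \code{\link{coverage_track}}.
#' @param ratio_threshold minimum normalized coverage (default 1.6).
#' @param min_bins minimum run length in bins (default 3).
#' @return BED-like data.frame: replicon, start, end, n_bins, mean_ratio.
#' @export
detect_duplications <- function(cov, ratio_threshold = 1.6, min_bins = 3) {
  calls <- list()
  for (r in unique(cov$replicon)) {
    sub <- cov[cov$replicon == r, ]
    sub <- sub[order(sub$start), ]
    hi <- sub$coverage >= ratio_threshold
    rle_ <- rle(hi)
    ends <- cumsum(rle_$lengths)
    starts <- ends - rle_$lengths + 1L
    for (k in which(rle_$values & rle_$lengths >= min_bins)) {
      run <- starts[k]:ends[k]
      calls[[length(calls) + 1L]] <- data.frame(
        replicon = r, start = sub$start[starts[k]],
        end = sub$end[ends[k]], n_bins = length(run),
        mean_ratio = mean(sub$coverage[run]), stringsAsFactors = FALSE)
    }
  }
  if (!length(calls))
    return(data.frame(replicon = character(0), start = integer(0),
                      end = integer(0), n_bins = integer(0),
                      mean_ratio = numeric(0)))
  do.call(rbind, calls)
}

#' Contact profile of a query region
#'
#' Mean normalized contact frequency between a set of query bins (e.g.
#' the bins of a plasmid) and every other genome bin. Query bins are
#' excluded from the output support, so the profile carries no trivial
#' self-contacts.
#'
#' @param cm an SCN \code{contact_matrix}.
#' @param query_bins bin indices (values of \code{cm$bins$bin}).
#' @return data.frame (bin, replicon, start, end, value) over non-query
#'   bins.
#' @export
contact_profile <- function(cm, query_bins) {
  if (!length(query_bins)) stopf("empty query")
  qi <- match(query_bins, cm$bins$bin)
  if (anyNA(qi)) stopf("query bins not in matrix")
  rows <- cm$m[qi, , drop = FALSE]
  prof <- colMeans(rows)
  keep <- setdiff(seq_len(nrow(cm$bins)), qi)
  cbind(cm$bins[keep, c("bin", "replicon", "start", "end")],
        value = prof[keep])
}

# Exhaustive maximal-contrast interval scan over a curve: returns the
# interval [a, b] maximizing (mean inside - mean outside) scaled by the
# effective segment size, so a sustained step beats one outlying bin.
scan_interval <- function(v) {
  m_ <- length(v)
  cs <- cumsum(v)
  tot <- cs[m_]
  best <- c(NA, NA, -Inf); best_score <- -Inf
  for (a in 1:m_) {
    b <- a:m_
    k <- b - a + 1
    n_out <- m_ - k
    s_in <- cs[b] - if (a > 1) cs[a - 1] else 0
    ctr <- ifelse(n_out == 0, -Inf,
                  s_in / k - (tot - s_in) / pmax(n_out, 1))
    score <- ctr * sqrt(k * n_out / m_)
    i <- which.max(score)
    if (score[i] > best_score) {
      best_score <- score[i]
      best <- c(a, b[i], ctr[i])
    }
  }
  list(best = best, score = best_score)
}

#' Observed/expected transform of a contact matrix
#'
#' Divides every intra-replicon entry by the mean contact at its bin
#' distance (circular replicons use circular bin distance when flagged)
#' and every inter-replicon entry by the mean of its replicon-pair block.
#' Removes the polymer distance-decay trend so that locus-specific
#' contact enrichments stand out.
#'
#' @param cm a \code{contact_matrix}.
#' @param circular optional named logical per replicon (default linear).
#' @return A \code{contact_matrix} of O/E ratios (state kept).
#' @export
oe_transform <- function(cm, circular = NULL) {
  m <- cm$m
  b <- cm$bins
  reps <- unique(b$replicon)
  for (r in reps) {
    i <- which(b$replicon == r)
    nb <- length(i)
    sub <- m[i, i, drop = FALSE]
    d <- abs(outer(seq_len(nb), seq_len(nb), "-"))
    if (isTRUE(circular[[r]])) d <- pmin(d, nb - d)
    expd <- tapply(sub, d, mean)
    e <- matrix(expd[as.character(d)], nb, nb)
    m[i, i] <- ifelse(e > 0, sub / e, 0)
    for (q in reps[reps != r]) {
      j <- which(b$replicon == q)
      blk <- cm$m[i, j, drop = FALSE]
      mu <- mean(blk)
      m[i, j] <- if (mu > 0) blk / mu else 0
    }
  }
  contact_matrix(m, b, state = cm$state)
}

#' Correlation-shift curve and breakpoint localization
#'
#' Scores every genome bin j by the Pearson correlation between its
#' contact vector on the query support (e.g. the bins of a plasmid) and
#' the query's aggregate contact profile (the average contact intensity
#' each query bin receives from the genome). A region whose DNA is also
#' carried by the query — the chromosomal copy of a plasmid-borne
#' duplication, collapsed onto one reference locus — inherits the query's
#' internal contact geometry and shows a sharp step in this curve; bins
#' elsewhere see the query only through diffuse background and score near
#' zero. The step's boundaries are localized per replicon by an
#' exhaustive maximal-contrast interval scan (both change points fitted
#' jointly, a sustained step scoring above any single outlying bin). A
#' breakpoint is reported only when the scan statistic exceeds the
#' 1 - \code{alpha_null} quantile of a permutation null (the same scan on
#' shuffled curves) and the inside-outside contrast reaches
#' \code{min_contrast}; a structureless curve therefore yields no call.
#' Empty query bins are excluded from the support.
#'
#' @param cm a \code{contact_matrix} (raw or SCN).
#' @param query_bins query bin indices (values of \code{cm$bins$bin}).
#' @param window query bins within \code{window} bins of j on the same
#'   replicon are excluded from j's correlation (guards self-proximity
#'   when query and target share a replicon; default 5).
#' @param min_contrast minimal inside-outside mean difference for a
#'   breakpoint call (default 0.2).
#' @param n_perm permutations for the null scan distribution
#'   (default 200; the permutation stream is internally seeded, so calls
#'   are deterministic).
#' @param alpha_null significance level on the permutation null
#'   (default 0.01).
#' @return data.frame (bin, replicon, start, end, correlation) over
#'   non-query bins, with attribute \code{"breakpoints"} (data.frame
#'   replicon, start, end, contrast; zero rows if no call).
#' @export
correlation_shift <- function(cm, query_bins, window = 5,
                              min_contrast = 0.2, n_perm = 200,
                              alpha_null = 0.01) {
  qi <- match(query_bins, cm$bins$bin)
  if (anyNA(qi)) stopf("query bins not in matrix")
  n <- nrow(cm$m)
  target <- setdiff(seq_len(n), qi)
  B <- cm$m[target, qi, drop = FALSE]
  live <- colSums(B) > 0
  if (sum(live) < 3) stopf("fewer than 3 informative query bins")
  qlive <- qi[live]
  ref_all <- colMeans(B[, live, drop = FALSE])  # query contact profile
  curve <- numeric(length(target))
  for (t in seq_along(target)) {
    j <- target[t]
    same <- cm$bins$replicon[qlive] == cm$bins$replicon[j] &
      abs(match(qlive, seq_len(n)) - j) <= window
    use <- which(!same)
    y <- cm$m[j, qlive[use]]
    x <- ref_all[use]
    curve[t] <- if (length(use) < 3 || stats::sd(x) == 0 ||
                    stats::sd(y) == 0) 0 else cor(x, y)
  }
  out <- cbind(cm$bins[target, c("bin", "replicon", "start", "end")],
               correlation = curve)
  # maximal-contrast interval scan, per replicon
  bps <- list()
  for (r in unique(out$replicon)) {
    sub <- out[out$replicon == r, ]
    sub <- sub[order(sub$start), ]
    v <- sub$correlation
    m_ <- length(v)
    if (m_ < 3) next
    res <- scan_interval(v)
    best <- res$best; best_score <- res$score
    # permutation null: the same scan on shuffled curves calibrates how
    # large a score arises without any genuine step
    null_scores <- with_seed(m_ + n_perm, vapply(
      seq_len(n_perm), function(b) scan_interval(sample(v))$score,
      numeric(1)))
    thresh <- stats::quantile(null_scores, 1 - alpha_null, names = FALSE)
    if (is.finite(best[3]) && best_score > thresh &&
        best[3] >= min_contrast) {
      bps[[length(bps) + 1L]] <- data.frame(
        replicon = r, start = sub$start[best[1]], end = sub$end[best[2]],
        contrast = best[3], stringsAsFactors = FALSE)
    }
  }
  attr(out, "breakpoints") <- if (length(bps)) do.call(rbind, bps) else
    data.frame(replicon = character(0), start = integer(0),
               end = integer(0), contrast = numeric(0))
  out
}
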