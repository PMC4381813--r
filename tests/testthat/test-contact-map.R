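test_that("PCR duplicates collapse on canonically ordered ends", {
  p <- toy_pairs(ref1 = c("a", "a", "a", "b", "b"),
                 pos1 = c(10L, 10L, 20L, 5L, 5L),
                 ref2 = c("a", "a", "a", "b", "b"),
                 pos2 = c(50L, 50L, 60L, 9L, 9L),
                 strand1 = "+", strand2 = "-")
  d <- dedup_pairs(p)
  expect_equal(nrow(d), 3L)
  expect_equal(attr(d, "removed"), 2L)

  # same physical pair given with swapped ends collapses to one
  p2 <- toy_pairs(ref1 = c("a", "a"), pos1 = c(10L, 50L),
                  ref2 = c("a", "a"), pos2 = c(50L, 10L),
                  strand1 = c("+", "-"), strand2 = c("-", "+"))
  expect_equal(nrow(dedup_pairs(p2)), 1L)

  # no duplicates: unchanged
  p3 <- toy_pairs(ref1 = "a", pos1 = 1L, ref2 = "a", pos2 = 2L)
  expect_equal(nrow(dedup_pairs(p3)), 1L)
  expect_equal(attr(dedup_pairs(p3), "removed"), 0L)
})

test_that("raw matrix counts each pair once, symmetric, mass conserved", {
  sch <- bp_bins(c(r = 40L), 10L)
  p <- toy_pairs(ref1 = rep("r", 4), pos1 = c(1L, 2L, 3L, 5L),
                 ref2 = rep("r", 4), pos2 = c(11L, 12L, 13L, 7L))
  cm <- build_matrix(p, sch)
  expect_equal(cm$m[1, 2], 3)          # three pairs joining bins 1-2
  expect_equal(cm$m[2, 1], 3)          # symmetry
  expect_equal(cm$m[1, 1], 1)          # self-bin pair on the diagonal
  ut <- upper.tri(cm$m, diag = TRUE)
  expect_equal(sum(cm$m[ut]), 4)       # mass = accepted pairs

  # unknown replicon rejected with count
  p2 <- toy_pairs(ref1 = c("r", "zz"), pos1 = c(1L, 1L),
                  ref2 = c("r", "zz"), pos2 = c(2L, 2L))
  cm2 <- build_matrix(p2, sch)
  expect_equal(cm2$meta$rejected, 1L)

  # uniform pairs: off-diagonal block equal within multinomial 99% CI
  set.seed(21)
  n <- 100000L
  pos1 <- sample.int(40L, n, TRUE) - 1L
  pos2 <- sample.int(40L, n, TRUE) - 1L
  cmu <- build_matrix(toy_pairs(rep("r", n), pos1, rep("r", n), pos2),
                      sch)
  off <- cmu$m[upper.tri(cmu$m)]
  p_cell <- 2 / 16                     # P(unordered pair in a given off cell)
  expect_true(all(abs(off - n * p_cell) <
                    2.576 * sqrt(n * p_cell * (1 - p_cell)) + 3))
})

test_that("SCN drives every non-empty row and column sum to one", {
  # one column pass suffices for this matrix
  s <- scn_normalize(toy_cm(matrix(c(2, 1, 1, 2), 2)))
  expect_equal(s$m, matrix(c(2, 1, 1, 2), 2) / 3)
  # identity is already doubly stochastic
  s3 <- scn_normalize(toy_cm(diag(3)))
  expect_equal(s3$m, diag(3))
  # random matrices: contract, idempotence, symmetry, support
  for (seed in 1:5) {
    set.seed(seed)
    m <- matrix(rpois(400, 4) * rbinom(400, 1, 0.8), 20)
    m <- m + t(m)
    s <- scn_normalize(toy_cm(m))
    expect_lt(max(abs(c(rowSums(s$m), colSums(s$m)) - 1)), 1e-6)
    expect_equal(s$m, t(s$m))
    expect_true(all((s$m > 0) == (m[rowSums(m) > 0, rowSums(m) > 0] > 0)))
    s2 <- scn_normalize(s)
    expect_lt(max(abs(s2$m - s$m)), 1e-6)
  }
  # empty bins are dropped and reported
  m <- matrix(c(1, 0, 2, 0, 0, 0, 2, 0, 4), 3)
  se <- scn_normalize(toy_cm(m))
  expect_equal(nrow(se$m), 2L)
  expect_equal(se$meta$dropped_bins, 2L)
  expect_error(scn_normalize(toy_cm(matrix(0, 2, 2))), "all-zero")
})

test_that("pearson map correlates matrix rows", {
  # identical rows correlate at 1; sign flip at -1
  m <- rbind(c(0.2, 0.3, 0.5), c(0.2, 0.3, 0.5), c(0.5, 0.3, 0.2))
  P <- pearson_map(toy_cm(m, state = "scn"))
  expect_equal(P$m[1, 2], 1.0)
  expect_equal(diag(P$m), rep(1, 3))
  expect_true(all(P$m >= -1 - 1e-12 & P$m <= 1 + 1e-12))
  expect_equal(P$m, t(P$m))

  # worked 3x3 case against the direct formula
  w <- matrix(c(.5, .3, .2, .3, .4, .3, .2, .3, .5), 3, byrow = TRUE)
  Pw <- pearson_map(toy_cm(w, state = "scn"))
  expect_equal(Pw$m[1, 2], cor(w[1, ], w[2, ]))
  expect_equal(Pw$m[1, 3], cor(w[1, ], w[3, ]))

  # constant row: entry set to 0 and flagged
  mc <- rbind(c(1, 1, 1), c(0.1, 0.5, 0.4), c(0.3, 0.3, 0.4))
  Pc <- pearson_map(toy_cm(mc, state = "scn"))
  expect_equal(Pc$m[1, 2], 0)
  expect_equal(Pc$meta$flagged_bins, 1L)
  expect_error(pearson_map(toy_cm(mc, state = "raw")), "SCN")
})

test_that("masking removes whole bins and commutes with building", {
  m <- matrix(1, 5, 5)
  cm <- toy_cm(m)
  masked <- mask_regions(cm, data.frame(replicon = "r", start = 1L,
                                        end = 3L))
  expect_equal(nrow(masked$m), 3L)
  expect_equal(masked$bins$bin, c(1L, 4L, 5L))
  # masking nothing is the identity
  expect_equal(mask_regions(cm, NULL)$m, cm$m)

  # mask-then-build == build-then-mask on bin-aligned regions
  sch <- bp_bins(c(r = 50L), 10L)
  set.seed(31)
  p <- toy_pairs(rep("r", 500), sample.int(50, 500, TRUE) - 1L,
                 rep("r", 500), sample.int(50, 500, TRUE) - 1L)
  keep <- !(p$pos1 %/% 10 %in% c(2, 3) | p$pos2 %/% 10 %in% c(2, 3))
  built_then_masked <- mask_regions(
    build_matrix(p, sch), data.frame(replicon = "r", start = 20L,
                                     end = 40L))
  masked_then_built <- build_matrix(p[keep, ], sch)
  kept_bins <- c(1L, 2L, 5L)
  expect_equal(built_then_masked$m,
               masked_then_built$m[kept_bins, kept_bins])
})

test_that("interspecies fraction counts cross-species label pairs", {
  sp1 <- c(rep("a", 997), rep("a", 3))
  sp2 <- c(rep("a", 997), rep("b", 3))
  p <- toy_pairs(rep("x", 1000), seq_len(1000), rep("x", 1000),
                 seq_len(1000) + 1L, species1 = sp1, species2 = sp2)
  expect_equal(interspecies_fraction(p), 0.003)
  p_intra <- toy_pairs("x", 1L, "x", 2L, species1 = "a", species2 = "a")
  expect_equal(interspecies_fraction(p_intra), 0)
  expect_error(interspecies_fraction(toy_pairs("x", 1L, "x", 2L)),
               "labels")
})

test_that("matrix TSV formats round-trip losslessly", {
  set.seed(41)
  m <- matrix(rpois(36, 3), 6); m <- m + t(m)
  bins <- data.frame(bin = 1:6, replicon = rep(c("u", "v"), each = 3),
                     start = rep(c(0L, 10L, 20L), 2),
                     end = rep(c(10L, 20L, 30L), 2))
  cm <- meta3cr:::contact_matrix(m, bins, state = "raw")
  f1 <- tempfile(); f2 <- tempfile()
  write_contact_matrix(cm, f1)
  b1 <- read_contact_matrix(f1)
  expect_equal(b1$m, cm$m)
  expect_equal(b1$bins$replicon, bins$replicon)
  expect_equal(b1$state, "raw")
  # sparse COO round-trip of a normalized (double-valued) matrix
  s <- scn_normalize(cm)
  write_contact_matrix_coo(s, f2)
  b2 <- read_contact_matrix_coo(f2)
  expect_identical(b2$m, s$m)
  expect_equal(b2$state, "scn")
})

test_that("observed/expected transform flattens a pure decay matrix", {
  n <- 30
  d <- abs(outer(1:n, 1:n, "-")); d <- pmin(d, n - d)
  m <- 1 / (1 + d)
  oe <- oe_transform(toy_cm(m), circular = c(r = TRUE))
  expect_true(all(abs(oe$m - 1) < 1e-12))
})
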