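test_that("genome simulation is reproducible and plants exact features", {
  cfg <- community_config(
    list(species_config("sp1", list(replicon_config("c1", 1000L)))))
  g1 <- simulate_genomes(cfg, 42)
  g2 <- simulate_genomes(cfg, 42)
  expect_identical(g1$seqs, g2$seqs)
  expect_equal(nchar(g1$seqs[["c1"]]), 1000L)

  # planted duplication: exact substring at both loci, both labelled
  cfgd <- community_config(
    list(species_config("sp1",
                        list(replicon_config("chr", 2000L),
                             replicon_config("pla", 600L)))),
    duplication = list(species = "sp1", src_replicon = "chr",
                       src_start = 100L, src_end = 240L,
                       dst_replicon = "pla", dst_start = 50L))
  gd <- simulate_genomes(cfgd, 7)
  expect_equal(substr(gd$seqs[["pla"]], 51, 190),
               substr(gd$seqs[["chr"]], 101, 240))
  expect_equal(gd$duplication$dst_end, 190L)

  # shared repeat: found at the 6 labelled loci
  cfgr <- community_config(
    list(species_config("a", list(replicon_config("ca", 20000L))),
         species_config("b", list(replicon_config("cb", 20000L)))),
    repeats = list(length = 500L, copies_per_species = 3L,
                   species = c("a", "b")))
  gr <- simulate_genomes(cfgr, 9)
  expect_equal(nrow(gr$repeats), 6L)
  rep_seq <- substr(gr$seqs[[gr$repeats$replicon[1]]],
                    gr$repeats$start[1] + 1L, gr$repeats$end[1])
  for (k in seq_len(nrow(gr$repeats))) {
    expect_equal(substr(gr$seqs[[gr$repeats$replicon[k]]],
                        gr$repeats$start[k] + 1L, gr$repeats$end[k]),
                 rep_seq)
  }
  # infeasible plant rejected
  expect_error(community_config(
    list(species_config("s", list(replicon_config("c", 100L),
                                  replicon_config("p", 50L)))),
    duplication = list(species = "s", src_replicon = "c",
                       src_start = 0L, src_end = 90L,
                       dst_replicon = "p", dst_start = 0L)),
    "does not fit")
})

test_that("contigs tile the genomes; chimera rate follows its setting", {
  cfg <- community_config(
    list(species_config("sp1", list(replicon_config("c1", 100000L)))))
  g <- simulate_genomes(cfg, 1)
  # exact tiling mode: 10 x 10 kb, full breadth of coverage
  ct <- simulate_contigs(g, seed = 2, fixed_length = 10000L)
  expect_equal(nrow(ct$contigs), 10L)
  expect_equal(sum(ct$contigs$chimeric), 0L)
  cov <- breadth_of_coverage(ct$pieces, c(c1 = 100000L))
  expect_equal(unname(cov), 1.0)
  # sequences are genuine genome slices
  pp <- ct$pieces[1, ]
  expect_equal(ct$seqs[[pp$contig]],
               substr(g$seqs[["c1"]], pp$start + 1L, pp$end))

  # chimeric fraction within the binomial 99% CI of its setting
  cfg2 <- community_config(
    list(species_config("a", list(replicon_config("ca", 2000000L))),
         species_config("b", list(replicon_config("cb", 2000000L)))))
  g2 <- simulate_genomes(cfg2, 3)
  ct2 <- simulate_contigs(g2, target_n50 = 15000, p_chimeric_join = 0.25,
                          seed = 4)
  n <- nrow(ct2$contigs)
  phat <- mean(ct2$contigs$chimeric)
  half <- 2.576 * sqrt(0.25 * 0.75 / n)
  expect_lt(abs(phat - 0.25), half + 1e-9)
  # every contig's pieces tile it exactly
  lens <- tapply(ct2$pieces$contig_end - ct2$pieces$contig_start,
                 ct2$pieces$contig, sum)
  expect_equal(as.numeric(lens[ct2$contigs$contig]),
               as.numeric(ct2$contigs$length))
})

test_that("pair library reproduces its configured composition", {
  cfg <- community_config(
    list(species_config("a", list(replicon_config("ca", 500000L, TRUE))),
         species_config("b", list(replicon_config("cb", 500000L, TRUE)))))
  g <- simulate_genomes(cfg, 5)

  # no chimeras when p_chimera = 0
  p0 <- simulate_pairs(g, library_config(n_pairs = 100000L,
                                         p_chimera = 0), seed = 6)
  expect_equal(sum(p0$label_species1 != p0$label_species2), 0L)

  # regular fraction within binomial 99% CI of 0.80
  p1 <- simulate_pairs(g, library_config(n_pairs = 100000L), seed = 7)
  phat <- mean(p1$type == "regular")
  expect_lt(abs(phat - 0.80), 2.576 * sqrt(0.8 * 0.2 / 100000))

  # interspecies fraction within binomial 99% CI of 0.0037
  isf <- interspecies_fraction(p1)
  expect_lt(abs(isf - 0.0037),
            2.576 * sqrt(0.0037 * 0.9963 / 100000))

  # label conservation: every end lies inside its labelled replicon
  rl <- setNames(g$replicons$length, g$replicons$replicon)
  expect_true(all(p1$pos1 >= 0 & p1$pos1 < rl[p1$ref1]))
  expect_true(all(p1$pos2 >= 0 & p1$pos2 < rl[p1$ref2]))

  # byte-identical determinism
  p2 <- simulate_pairs(g, library_config(n_pairs = 100000L), seed = 7)
  expect_identical(p1, p2)
})

test_that("religation separations recover the configured decay exponent", {
  cfg <- community_config(
    list(species_config("s", list(replicon_config("c", 1000000L, TRUE)))))
  g <- simulate_genomes(cfg, 8)
  lib <- library_config(n_pairs = 1000000L, p_regular = 0,
                        p_chimera = 0, p_trans_replicon = 0, alpha = 1.0)
  p <- simulate_pairs(g, lib, seed = 9)
  dc <- distance_decay(p, c(c = 1000000L), circular = TRUE,
                       dmin = 1000, dmax = 400000)
  expect_lt(abs(attr(dc, "alpha") - 1.0), 0.1)

  # a steeper library fits steeper
  lib2 <- library_config(n_pairs = 300000L, p_regular = 0,
                         p_chimera = 0, p_trans_replicon = 0, alpha = 1.5)
  p2 <- simulate_pairs(g, lib2, seed = 10)
  dc2 <- distance_decay(p2, c(c = 1000000L), circular = TRUE,
                        dmin = 1000, dmax = 400000)
  expect_lt(abs(attr(dc2, "alpha") - 1.5), 0.15)
})

test_that("pairs re-map onto contig coordinates exactly", {
  cfg <- community_config(
    list(species_config("s", list(replicon_config("c", 50000L, TRUE)))))
  g <- simulate_genomes(cfg, 11)
  ct <- simulate_contigs(g, seed = 12, fixed_length = 5000L)
  p <- simulate_pairs(g, library_config(n_pairs = 5000L, p_chimera = 0),
                      seed = 13)
  cp <- map_pairs_to_contigs(p, ct)
  expect_true(all(cp$ref1 %in% ct$contigs$contig))
  lens <- setNames(ct$contigs$length, ct$contigs$contig)
  expect_true(all(cp$pos1 >= 0 & cp$pos1 < lens[cp$ref1]))
  # spot check: the mapped position recovers the genomic base
  k <- 17
  piece <- ct$pieces[ct$pieces$contig == cp$ref1[k] &
                       ct$pieces$contig_start <= cp$pos1[k] &
                       ct$pieces$contig_end > cp$pos1[k], ]
  expect_equal(piece$start + (cp$pos1[k] - piece$contig_start),
               p$pos1[k])
})

test_that("pair TSV round-trips", {
  cfg <- community_config(
    list(species_config("s", list(replicon_config("c", 10000L)))))
  g <- simulate_genomes(cfg, 14)
  p <- simulate_pairs(g, library_config(n_pairs = 500L, p_chimera = 0,
                                        p_trans_replicon = 0), seed = 15)
  tmp <- tempfile(fileext = ".tsv")
  write_pairs(p, tmp)
  back <- read_pairs(tmp)
  expect_equal(back$pos1, p$pos1)
  expect_equal(back$ref2, p$ref2)
  expect_equal(back$label_species1, p$label_species1)
})
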