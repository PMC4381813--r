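test_that("breadth of coverage is the length of the interval union", {
  # exact tiling covers everything
  pieces <- data.frame(replicon = "g", start = c(0L, 400L),
                       end = c(600L, 1000L))
  expect_equal(unname(breadth_of_coverage(pieces, c(g = 1000L))), 1.0)
  # single partial contig
  p2 <- data.frame(replicon = "g", start = 0L, end = 250L)
  expect_equal(unname(breadth_of_coverage(p2, c(g = 1000L))), 0.25)
  # monotone under adding contigs
  p3 <- rbind(p2, data.frame(replicon = "g", start = 500L, end = 700L))
  expect_gte(unname(breadth_of_coverage(p3, c(g = 1000L))),
             unname(breadth_of_coverage(p2, c(g = 1000L))))
  # overlap is not double counted
  p4 <- data.frame(replicon = "g", start = c(0L, 100L),
                   end = c(300L, 200L))
  expect_equal(unname(breadth_of_coverage(p4, c(g = 1000L))), 0.3)
})

test_that("purity and ARI score a partition against species truth", {
  contigs <- list(
    contigs = data.frame(contig = c("c1", "c2", "c3", "c4"),
                         length = c(1e6, 1e4, 5e5, 5e5),
                         chimeric = FALSE),
    pieces = data.frame(contig = c("c1", "c2", "c3", "c4"),
                        piece = 1L,
                        species = c("A", "B", "B", "B"),
                        replicon = c("ra", "rb", "rb", "rb"),
                        start = 0L, end = 1L,
                        contig_start = 0L, contig_end = 1L))
  # perfect binning
  tab <- data.frame(contig = c("c1", "c2", "c3", "c4"),
                    community = c(1L, 2L, 2L, 2L),
                    agreement = 1,
                    length = contigs$contigs$length)
  res <- community_purity(tab, contigs)
  expect_true(all(res$per_community$purity == 1))
  expect_equal(res$ari, 1.0)

  # a 10 kb species-B contig inside a 1 Mb species-A community
  tab2 <- data.frame(contig = c("c1", "c2"), community = 1L,
                     agreement = 1, length = c(1e6, 1e4))
  res2 <- community_purity(tab2, contigs)
  expect_equal(res2$per_community$purity[1], 1e6 / (1e6 + 1e4),
               tolerance = 1e-6)
  expect_equal(res2$per_community$dominant_species[1], "A")

  # chimeric contigs are excluded but counted
  contigs$pieces <- rbind(contigs$pieces,
                          data.frame(contig = "c4", piece = 2L,
                                     species = "A", replicon = "ra",
                                     start = 5L, end = 6L,
                                     contig_start = 1L, contig_end = 2L))
  res3 <- community_purity(tab, contigs)
  expect_equal(res3$n_chimeric_excluded, 1L)

  # random assignment of two balanced species: ARI near zero
  set.seed(151)
  aris <- replicate(20, {
    ctg <- list(
      contigs = data.frame(contig = sprintf("c%03d", 1:200),
                           length = 1000, chimeric = FALSE),
      pieces = data.frame(contig = sprintf("c%03d", 1:200), piece = 1L,
                          species = rep(c("A", "B"), each = 100),
                          replicon = "r", start = 0L, end = 1L,
                          contig_start = 0L, contig_end = 1L))
    tabr <- data.frame(contig = sprintf("c%03d", 1:200),
                       community = sample(1:2, 200, TRUE),
                       agreement = 1, length = 1000)
    community_purity(tabr, ctg)$ari
  })
  expect_lt(abs(mean(aris)), 0.05)
})

test_that("N50 follows the at-least-half-the-total rule", {
  expect_equal(n50(c(10, 10, 10, 10)), 10)
  expect_equal(n50(c(1, 2, 3, 4, 10)), 10)
  expect_equal(n50(c(5, 5, 10)), 10)
  expect_equal(n50(c(2, 2, 2, 3)), 2)
  expect_error(n50(numeric(0)), "empty")
  # oracle: exhaustive check of the definition on random cases
  set.seed(161)
  for (k in 1:20) {
    lens <- sample(1:50, sample(1:12, 1), replace = TRUE)
    cand <- sort(unique(lens), decreasing = TRUE)
    want <- max(cand[vapply(cand, function(L)
      sum(lens[lens >= L]) >= sum(lens) / 2, logical(1))])
    expect_equal(n50(lens), want)
  }
})

test_that("chimera rate counts multi-species contigs by count and length", {
  contigs <- list(
    contigs = data.frame(contig = sprintf("c%d", 1:10),
                         length = rep(100L, 10), chimeric = FALSE),
    pieces = data.frame(contig = sprintf("c%d", 1:10), piece = 1L,
                        species = "A", replicon = "r",
                        start = 0L, end = 100L,
                        contig_start = 0L, contig_end = 100L))
  expect_equal(chimera_rate(contigs)$by_count, 0)
  contigs$pieces$species[1] <- "A"
  contigs$pieces <- rbind(contigs$pieces,
                          data.frame(contig = "c1", piece = 2L,
                                     species = "B", replicon = "q",
                                     start = 0L, end = 50L,
                                     contig_start = 100L,
                                     contig_end = 150L))
  cr <- chimera_rate(contigs)
  expect_equal(cr$by_count, 0.1)
  expect_equal(cr$n_chimeric, 1L)
  expect_equal(cr$chimeric_bp, 100L)

  # simulator rate within the binomial 99% CI of its setting
  cfg <- community_config(
    list(species_config("a", list(replicon_config("ca", 1500000L))),
         species_config("b", list(replicon_config("cb", 1500000L)))))
  g <- simulate_genomes(cfg, 171)
  ct <- simulate_contigs(g, target_n50 = 4000, p_chimeric_join = 0.05,
                         seed = 172)
  n <- nrow(ct$contigs)
  expect_gt(n, 400)
  cr2 <- chimera_rate(ct)
  expect_lt(abs(cr2$by_count - 0.05),
            2.576 * sqrt(0.05 * 0.95 / n))
  # flags agree with the truth intervals
  expect_equal(cr2$n_chimeric, sum(ct$contigs$chimeric))
})

test_that("the evaluation report bundles all truth-label scores", {
  cfg <- community_config(
    list(species_config("a", list(replicon_config("ca", 100000L))),
         species_config("b", list(replicon_config("cb", 100000L)))))
  g <- simulate_genomes(cfg, 181)
  ct <- simulate_contigs(g, seed = 182, fixed_length = 10000L)
  tab <- data.frame(contig = ct$contigs$contig,
                    community = as.integer(factor(
                      tapply(ct$pieces$species, ct$pieces$contig, `[`, 1)[
                        ct$contigs$contig])),
                    agreement = 1, length = ct$contigs$length)
  rep_ <- eval_report(tab, ct, g)
  expect_equal(rep_$ari, 1.0)
  expect_equal(unname(rep_$coverage), c(1.0, 1.0))
  expect_equal(rep_$n50, 10000L)
  expect_equal(rep_$chimera$by_count, 0)
  tmp <- tempfile()
  write_eval_report(rep_, tmp)
  expect_true(any(grepl("chimera_by_count", readLines(tmp))))
})
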