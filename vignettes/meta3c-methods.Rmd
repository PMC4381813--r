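---
title: "Methods: contact-driven deconvolution and 3D reconstruction of mixed microbial genomes"
author: "meta3cr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contact-driven deconvolution and 3D reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the approach

Chromosome conformation capture (3C/Hi-C) measures how often two DNA loci
touch in space. Applied to a mixed microbial community (meta3C), the decisive
property is that crosslinking happens inside intact cells: almost every
ligation joins two fragments of the *same* cell. Contact frequency therefore
carries a species signal — DNA from one organism contacts itself orders of
magnitude more often than DNA from another — on top of the intra-genome
polymer signal, where contact probability decays with genomic distance
roughly as $P(s) \propto s^{-\alpha}$.

`meta3cr` implements the computational side of this idea end to end:

1. **Coordinates** — in-silico restriction digestion builds the fragment map
   (`digest_genomes()`), and fragments or fixed windows define matrix bins
   (`make_bins()`, `bp_bins()`).
2. **Contact maps** — mapped pair positions become a symmetric bin×bin count
   matrix (`build_matrix()`), deduplicated (`dedup_pairs()`) and balanced by
   sequential component normalization (`scn_normalize()`).
3. **Binning** — contigs are chunked to equalize node size, a weighted
   contact graph is built over chunks, and Louvain modularity optimization
   groups them into species-level communities (`chunk_contigs()`,
   `build_graph()`, `louvain_partition()`, `assign_contigs()`).
4. **3D reconstruction** — the normalized map becomes a graph whose edge
   weights are inverse contacts; all-pairs shortest paths give a metric;
   classical distance-geometry scaling embeds it in 3D (`embed_matrix()`).
5. **Features** — per-bin coverage exposes collapsed segmental duplications
   (`detect_duplications()`); a correlation-score scan against a query
   replicon localizes duplication breakpoints (`correlation_shift()`).
6. **Evaluation** — with the bundled simulator, every inference is scored
   against planted truth (`eval_report()`).

Because real meta3C libraries are large sequencing experiments, the package
ships a first-class simulator (`simulate_genomes()`, `simulate_contigs()`,
`simulate_pairs()`) that reproduces the statistical structure these analyses
rely on, with truth labels that the inference code never reads.

## The simulator: what it emulates, and what it does not

A simulated library mixes three kinds of pairs, drawn from a multinomial with
the configured marginal fractions:

* **Regular pairs** (default 80%): ordinary shotgun-like inserts, normal
  insert length (default 500 ± 50 bp), inward orientation. Mixed-community
  3C libraries really are dominated by such pairs, which is what makes
  de-novo assembly from the same library possible.
* **Religation pairs**: the 3C signal proper. The genomic separation $s$ of
  the two ends follows the polymer decay $P(s)\propto s^{-\alpha}$ with
  $\alpha = 1$ by default, truncated below `min_dist` (default 256 bp, about
  one restriction fragment of a 4-base cutter — separations below one
  fragment are not resolvable by the assay) and above half the replicon for
  circular replicons. Circular replicons use circular distance, which is what
  produces the counter-diagonal of a circular chromosome's map and its closed
  ring in 3D. A fraction `p_trans_replicon` (default 0.05) of religation
  events joins two replicons of the same cell, uniformly — this is how a
  plasmid co-compartmentalizes with its host chromosome.
* **Chimeric pairs** (default 0.37%): crosslinks between cells, joining two
  species drawn by abundance. This is the experimentally observed
  cross-species background of a mixed-culture library.

The source of the decay exponent default deserves a note: published meta3C
work does not report a fitted $\alpha$ for its libraries, so $\alpha = 1$ —
the generic exponent of a crumpled polymer at these scales — is a free
default, and `distance_decay()` recovers whatever value the generator used
to within ±0.1 at $10^6$ pairs.

**Planted duplications.** A community may carry a segmental duplication: an
interval of one replicon copied verbatim into another (the F'-plasmid
situation, where an episome carries a large chromosomal region). Pairs are
generated on the true two-copy genomes; by default (`collapse_duplicates =
TRUE`) mapped positions falling in the second copy are then remapped onto the
single-copy source interval. This emulates read mapping against a one-copy
reference, and is the mechanism behind both observable signatures: the
region's apparent coverage doubles, and it inherits the plasmid's contact
geometry.

**What the simulator does not model**: GC or mappability bias, sequencing
error, a replication-origin coverage gradient, genuine 3D nuclear
organization (trans contacts are uniform), or a real assembler (contigs are
genome slices with an optional cross-species join). Tests passing on this
generator therefore certify the pipeline's statistical machinery — balancing,
graph clustering, embedding, change-point detection — under a known model,
not robustness to every bias of real libraries.

## Contact maps and SCN

`build_matrix()` counts each deduplicated pair once into the symmetric
bin×bin matrix (self-bin pairs on the diagonal). Sequential component
normalization then divides every column by its sum and every row by its sum,
iterating until the largest deviation of any row or column sum from 1 is
below `tol` (default 1e-6, at most `max_iter` sweeps). Empty bins are dropped
first and reported; symmetry is restored afterwards by averaging with the
transpose, which preserves the sums contract. SCN removes per-bin visibility
biases (fragment density, mappability) so that downstream steps see relative
contact structure. The diagonal is kept through SCN — it carries no inter-bin
information, but removing it would change the marginals the contract is
stated on — and the 3D graph construction ignores it anyway. On structured
end-to-end matrices SCN can need somewhat more than 100 sweeps to pass 1e-6,
so the pipeline default is `max_iter = 300`.

`pearson_map()` correlates full matrix rows (diagonal included, matching the
usual construction of correlation maps); `exclude_diag = TRUE` is available
for the variant that drops the two self entries.

## Binning by modularity

Contigs longer than 2.5 kb are split into `floor(L / 2500)` equal chunks so
that every graph node represents a comparable amount of sequence — otherwise
long contigs accumulate proportionally more contacts and dominate the
clustering. Edges are raw inter-chunk pair counts; chunking itself is the
size normalization, so weights are not length-scaled.

Community detection uses Louvain modularity optimization (igraph) with a
resolution parameter $r$ and seeded restarts (`repeats`, best modularity
kept). One behavior matters in practice: at the conventional $r = 1$,
modularity on a megabase bacterial genome is maximized by splitting the
genome into a handful of *intra*-genome domains — each pure, but several per
species. This is the classic resolution behavior of modularity, and published
meta3C analyses likewise had to adjust their community-detection parameter
for a defined three-species mixture. For species-level deconvolution the
pipeline therefore defaults to $r = 0.1$; at that setting the bundled
three-species benchmark yields exactly one community per species with
length-purity 1.0 and ARI 1.0 against truth, and raising $r$ through
$\{0.5, 1, 2, 5, 10\}$ monotonically increases the community count. The
function-level default of `louvain_partition()` remains $r = 1$.

Chunk calls are reconciled per contig by length-weighted majority; a contig
whose leading community holds less than half its length (or an exact tie) is
left unattributed rather than guessed.

## 3D reconstruction

The normalized map is converted to a graph with edge weight $1/m_{ij}$ for
every positive off-diagonal contact: frequent contact = short edge. All-pairs
shortest paths over this graph (igraph, non-negative weights — equivalent by
contract to Floyd–Warshall) yield a distance matrix, embedded by classical
scaling: double-center the squared distances, take the three leading
non-negative eigenpairs, coordinates are eigenvector·√eigenvalue. Negative
eigenvalues — the non-Euclidean part of shortest-path metrics — are truncated
to zero and their total magnitude reported; the normalized RMS discrepancy
between input and embedded distances is reported as `stress`. For distances
realizable in ≤3 dimensions the embedding is exact (stress ~ 0), which the
tests verify on closed-form cases.

Two conventions make outputs reproducible: eigenpairs are ordered by
eigenvalue, and each axis is flipped so its third moment is non-negative.
Disconnected maps (after masking, or without cross-species background) are
embedded per connected component, largest first; components with fewer than
4 bins are skipped.

`ring_diagnostics()` quantifies the hallmark of a circular chromosome: with
bins in genomic order, the gap between the first and last embedded bin
(closure gap) is compared with the median adjacent-bin gap. A circular
simulation closes (ratio < 3 in the benchmark); a linear one does not.

## Duplication detection and breakpoint localization

Coverage per bin (both pair ends counted) is normalized by the genome-wide
median over non-empty bins, so single-copy sits at 1 and a collapsed two-copy
region near 2. `detect_duplications()` calls maximal runs of at least
`min_bins` (default 3) bins at or above `ratio_threshold` (default 1.6,
between the one- and two-copy levels).

`correlation_shift()` localizes which chromosomal region a query replicon
(e.g. an F'-like plasmid) shares. The score of bin $j$ is the Pearson
correlation between $j$'s contact vector *on the query's bins* and the
query's aggregate contact profile. The design rationale: the unambiguous
signature of the collapsed copy is its strong, structured contact block with
the query replicon itself. A genome-wide row correlation smears this step
over the polymer decay length (neighboring bins see the region through decay
contacts), and Pearson's scale invariance can even invert it, because
in-region rows carry a high-variance query block that suppresses their
correlation with a profile whose dominant feature they also share. Scoring on
the query support sidesteps both effects and leaves a near-rectangular step.

The step's two boundaries are fitted jointly by an exhaustive interval scan
maximizing (mean inside − mean outside) scaled by $\sqrt{k\,(m-k)/m}$ — the
size factor makes a sustained 10-bin step outrank a single outlying bin. A
call requires the scan statistic to exceed the 99th percentile of a
permutation null (200 internally-seeded shuffles of the curve) and an
inside–outside contrast of at least `min_contrast` (default 0.2); a
structureless curve yields no call. On the bundled F'-like benchmark (500 kb
chromosome, 200 kb plasmid carrying a 60 kb copy, 5 kb bins, 4×10⁵ pairs)
both boundaries land within 2 bins of truth across seeds. Masking the
duplicated region (`mask_regions()`) removes the artificial plasmid–chromosome
bridge, and the plasmid's mean embedded distance to the chromosome increases
— the geometric counterpart of the same signature.

## Evaluation against truth

`eval_report()` replaces reference-alignment assessment with the simulator's
labels: breadth of coverage per replicon (union of contig source intervals /
replicon length, via IRanges), per-community length purity and dominant
species, adjusted Rand index between the contig→community and contig→species
maps (mclust), N50 by the at-least-half-the-total rule, and the
chimeric-contig rate by count and by length. Chimeric contigs have no single
source species: they are excluded from purity and ARI and accounted
separately, and fractions are always reported alongside their counts.

## Problem sizes and reproducibility

The bundled benchmarks are desk-scale by design: the three-species mix is
3×~1 Mb genomes (one species with a 0.5 Mb second replicon) and 2×10⁶ pairs
at 10 kb bins; decay-exponent recovery uses 10⁶ religation pairs on a 1 Mb
circular replicon; the duplication benchmark is 0.7 Mb with 4×10⁵ pairs. At
these sizes the complete pipeline — simulation through evaluation — runs in
about a minute on one core, and every result in this vignette is recomputed
by the test suite (`tests/testthat/`, including `test-acceptance.R`) and by
`scripts/acceptance.R`; nothing here is quoted from elsewhere.

Determinism is treated as part of the interface: one global seed, per-stage
sub-seeds derived from it, RNG state restored after every seeded block, and
byte-identical artifacts on re-run (verified by checksum in the tests). The
Louvain restarts, the permutation null of the breakpoint scan, and every
simulator draw all run under this discipline.

## Known limitations

* Trans-replicon and cross-species contacts are uniform; analyses that
  depend on genuine 3D co-location profiles (e.g. profile-similarity host
  assignment across species) are exercised only through the direct-contact
  signal the simulator does provide.
* SCN is the only balancing offered; explicit-factor corrections (GC,
  mappability) are out of scope.
* Non-palindromic restriction sites are matched on the forward strand only
  (the common 3C enzymes HpaII, DpnII and HaeIII are palindromic).
* The chunk→contig majority rule and the unattributed threshold (0.5) are
  deliberately simple; highly fragmented or repeat-dense assemblies may need
  the thresholds exposed on `assign_contigs()`.
* Shortest-path metrics are generally non-Euclidean; the reported negative
  eigenvalue mass and stress should be inspected before interpreting fine
  geometric detail of an embedding.
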