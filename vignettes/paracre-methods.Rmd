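---
title: "Methods: analysing cis-regulation in paralogous gene families"
author: "paracre"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: analysing cis-regulation in paralogous gene families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paracre)
```

## The problem

Recently expanded gene families -- such as the killer-cell lectin-like
receptor clusters of rodents -- consist of many near-identical paralogous
loci. Standard epigenomic pipelines fail on them twice over: short reads
multimap among the paralogs and are discarded by mapping-quality filters,
and per-locus signal tracks cannot be compared because each paralog lives
at its own coordinates. `paracre` implements the analysis layer for this
situation: a consensus coordinate system shared by all paralogs, a
normalized-alignment-score rescue rule for multimapping reads,
element-level quantification of transposase-accessibility and TSS signal,
binarized single-cell co-expression odds ratios, matched-background
chromatin-contact enrichment, and conserved-element / motif / homology
scanning. Every analysis is paired with a synthetic-data generator that
produces inputs with known truth, so the pipeline can be validated end to
end.

## The synthetic family generator

`generate_paralog_family()` duplicates a random ancestor into `n`
paralogs, each diverged by per-base substitutions (uniform over the three
alternative bases) and short indels with geometric lengths. The defaults
-- 8 paralogs, 3 kb ancestor, 5% substitutions, 0.5% indels of mean
length 2 -- describe a young family in which paralogs are still ~95%
identical, the regime in which multimapping is a real problem. Three
properties are structural, not statistical:

* the true multiple alignment is **built constructively from the mutation
  log**, never re-estimated with an aligner, so tests of the consensus and
  projection code are independent of any alignment heuristic;
* every paralog is reconstructible from the ancestor plus its log entries,
  which the test suite asserts;
* each generator draws from its own RNG stream keyed by
  `(master seed, generator name)`, so adding a generator never perturbs
  another's output at the same seed.

`plant_conserved_element()` overwrites a homologous ancestor interval with
an element: verbatim in carrier paralogs, decayed by per-base substitution
in the rest. Indels overlapping the interval are removed from all
paralogs, so an element is never split in a carrier and its footprint is
contiguous in every paralog -- the simplification that keeps the truth
coordinate maps exact. What the generator deliberately does *not* emulate:
selection, rearrangement, gene conversion, or sequencing-quality
artefacts. Passing tests therefore demonstrate correctness of the
algorithms under a clean divergence model, not robustness to every
pathology of real libraries.

## Consensus projection

`build_consensus()` applies a per-column majority rule (threshold 0.5,
gaps counted in the denominator); columns whose consensus character is the
gap are removed, and `kept_columns` records the survivors. Ties are
resolved deterministically: a non-gap character beats the gap, a tie
between two bases yields `N`. `build_coordinate_map()` then maps every
ungapped paralog base to the consensus position of its column (`NA` where
the column was dropped), and `project_signal()` carries per-bp values
across. Because each base maps to at most one consensus position, signal
mass over mapped positions is conserved exactly -- an invariant the tests
assert literally, not approximately.

At the default 5% divergence the consensus reproduces the ancestor up to
the occasional ambiguous column (an `N` where five or more of eight
paralogs happen to be mutated); such columns are kept, so coordinate maps
and round trips remain exact regardless.

`normalize_and_stack()` scales every projected track to a common sum
(default 1e4 -- the method only requires equality across tracks, not a
particular constant) and adds a uniform per-bp noise floor. The default
noise is `noise_floor(3e7, 75, 3e9)` = 1.5 per bp, the mean genomic
coverage of a 30-million-pair, 75 bp library on a 3 Gb genome; it
prevents tracks with very few reads from exploding after fixed-sum
normalization.

Internally all coordinates are 1-based inclusive, the R and Bioconductor
convention; BED and bedGraph files on disk are written and read 0-based
half-open.

## Multimapper rescue

A read aligned against every candidate locus receives a raw alignment
score `AS` (0 = perfect; mismatches and gaps subtract), normalized as
`nAS = AS / read_length`. The rescue rule (`rescue_assign()`): placements
with `nAS < -0.1` are removed; if none survive the read is discarded; the
read is assigned to every placement achieving the maximum surviving score
(all of them when tied, the single best otherwise); and a target placement
strictly below the read's best score anywhere is never assigned. Cutoff
comparisons are done in exact integer arithmetic
(`score * denom >= num * read_length`), so a read at exactly `nAS = -0.1`
is retained regardless of floating-point representation.

Scoring uses an authored affine-gap fitting alignment (whole read against
the best-scoring substring of each locus; gap of length *k* costs
`open + k * extend`; match 0, mismatch -6, open 5, extend 3 -- the
end-to-end short-read convention), implemented in C++ for speed. The test
suite cross-checks it against `Biostrings::pairwiseAlignment`
(`type = "global-local"`), a fully independent dynamic-programming engine,
and requires decision-level agreement on 100% of 2000 synthetic reads.
Mate pairs are treated as fragments upstream of this package; the rescue
rule itself is per-read.

## ATAC signal

Each transposase insertion event is extended 75 bp both ways into a 150 bp
pseudo read; pileups are divided by library depth (scale 1e7). Element
counting uses any-overlap (at least 1 bp, half-open) against
non-overlapping element intervals. Cross-sample normalization scales every
sample's column to the raw total of the *reference* sample -- the sample
whose total is the median (lower median for an even count), so the target
is always an actual sample. Insertion events are counted per event, two
per fragment for paired data.

## TSS clustering and filtering

The alignment architecture filter removes records with template length
> 10 kb, soft clipping > 3 bp, or any mismatch -- all strict boundaries,
covered by boundary tests. UMI deduplication keeps the first alignment of
each UMI within a 100,000-record sliding window of a position-sorted
table.

`powerlaw_normalize()` fits the log-log reverse-cumulative count
distribution within `fit_range = c(5, 1000)` by least squares and maps
each raw count onto a reference power law with exponent -1.2 scaled to
1e6 total tags (the reference intercept comes from
`K = T / zeta(alpha)`). The regression details are this package's
documented choice; the mapping is monotone, and on counts drawn from the
reference law itself it reduces to a simple rescale, which the tests
check.

`distclu()` seeds clusters at positions whose normalized signal reaches 2
in at least `min_samples` samples and single-links same-strand seeds
within 50 bp; singleton clusters are kept only when their pooled signal
exceeds 4 (strict). The pooled (summed over samples) signal is used for
the singleton rule; per-sample variants would only differ for singletons
near the boundary. `two_step_peaks()` intersects a loose pass
(`min_samples = 1`) with a strict pass (all samples), keeps loose
boundaries (strict-pass widths are over-conservative), and lets an
allowlist of condition-specific promoters bypass the strict requirement.
The cap-signature filter retains clusters with strictly more than 70% of
reads carrying an unencoded 5' G; a read counts as capped if its 5' end
carries at least one such G, the simplest reading of the signature.

## Co-expression odds ratios

Counts are binarized at one read. For genes *x*, *y* the cells partition
into `a` (x-y-), `b` (x-y+), `c` (x+y-), `d` (x+y+), and the odds ratio
`(d/c)/(b/a) = ad/bc` measures co-occurrence relative to independence.
Zero-product tables are flagged (`Inf` / undefined), never
continuity-corrected -- the Fisher p-value is unaffected. `fisher_exact()`
sums hypergeometric probabilities of all tables with the observed margins
no more probable than the observed one (relative tolerance 1e-7), and is
verified against an independent binomial-coefficient enumeration for every
table with `n <= 40` and against `stats::fisher.test` on random tables.
Benjamini-Hochberg adjustment is applied across all pairs of a sample;
across samples the heatmap entry is the mean odds ratio and the *largest*
(least significant) FDR, generalized to the maximum over more than two
samples.

The cell-matrix generator plants a pair's joint distribution as the unique
2x2 table with the requested marginals and odds ratio -- the root of the
Plackett quadratic inside the Frechet interval, found by `uniroot` on the
log odds ratio. For marginals strictly inside (0, 1) every finite positive
odds ratio is attainable (the odds ratio is a continuous increasing
bijection of the joint probability over the open interval), so feasibility
errors arise only for degenerate requests (OR of 0 or infinity, marginals
at 0 or 1).

## Contact-matrix enrichment

`vc_normalize()` divides each contact by the product of its anchors'
coverage factors `v_i = rowsum_i / mean(positive rowsums)`; scaling by the
mean keeps the normalized matrix on the raw scale (the external pipelines
this emulates do not print their constant). Hotspot strength is the mean
normalized frequency inside an inner rectangle versus the frame between it
and an outer rectangle; rectangles are user inputs. Background selection
for a foreground pair keeps candidates within 5 kb of its genomic distance
(inclusive), excludes all declared foregrounds, and takes the `k = 10`
candidates nearest in the 2D space of (centromeric, telomeric) anchor
coverage -- the cross-sample mean of per-sample coverage profiles each
scaled to 100,000 -- with deterministic tie-breaking. Enrichment tests
are two-tailed Welch t-tests with BH adjustment across the declared
family.

The simulator draws counts as
`Poisson(N * c_i * c_j * max(|i-j|,1)^-decay * h)`. The validation design
uses a 3x3-bin hotspot in a 100-bin matrix: a planted hotspot inflates its
own anchors' row sums, so vanilla-coverage normalization slightly deflates
the recovered ratio, and with this geometry the expectation-level
(noise-free) ratio is 2.92 for a planted multiplier of 3 -- a ~3% design
bias, small against the 15% acceptance band. Larger hotspots relative to
the matrix would bias the ratio further down; this is a property of
coverage normalization, not of the estimator.

## Conservation and motifs

`column_identity()` reports each column's modal nucleotide frequency with
gaps in the denominator but never modal (conservation refers to
nucleotides). `conserved_runs()` reports maximal runs of at least 10
columns at >= 90% identity, both bounds inclusive. Exact boundary
recovery of a planted element requires boundary contrast -- a conserved
element flanked by conserved background is indistinguishable from a longer
element -- so the validation plants short high-decay guard elements at
both flanks, making the planted edges sharp by construction.

`pwm_scan()` scores log2 odds against the background with a 0.01
pseudocount per cell, discretized at 1e-3; the exact p-value of a score is
its tail probability under the background base distribution, computed by
dynamic-programming convolution of the per-position score distributions
(the construction FIMO-style scanners use) and verified against complete
4^k enumeration for motifs up to width 8. Hits with `p < 0.01` are
reported; both strands are scanned by default (switchable).

`window_identity()` slides a 100-column window over a pairwise alignment
(gaps count as mismatches) and highlights merged regions longer than 100
columns with identity strictly above 70%. `homology_search()` is a
dot-plot-style seed-and-extend: exact shared 8-mers seed ungapped
diagonals, x-drop extension with a mismatch penalty whose break-even
equals the identity threshold, merged segments filtered at
`>= min_len` and `>= min_identity` (defaults 100 bp, 60%; the companion
35 bp screen is the same call with a smaller `min_len`). Inverted
homology searches the reverse complement and reports coordinates on the
original strand. Recovery of planted homologous segments is the
correctness surface; identity with any particular dot-plot tool is not.

## Problem sizes and numerical choices

The test and validation runs use deliberately desk-scale instances: 2000
reads against 8 paralogs of ~1.2 kb for the rescue-versus-oracle sweep,
complete enumeration of all 2x2 tables with `n <= 40` for the Fisher
check, 50 replicate seeds per planted odds ratio at 5000 cells, and 20
replicate 100-bin contact matrices for hotspot recovery. Tolerances
follow the statistic: exact (`identical`) for arithmetic identities, mass
conservation and boundary rules; 3-standard-error bands for stochastic
parameter recovery; nominal-rate plus three binomial standard errors for
calibration checks.

## Limitations

* The divergence model has no selection or rearrangement; homology and
  conservation results on real loci will include repeat- and
  conversion-driven structure the generator does not produce.
* The rescue rule assumes integer alignment scores with maximum 0; other
  scoring schemes require re-expressing the cutoff.
* `powerlaw_normalize()` assumes the count distribution is roughly
  power-law in the fitted range; heavy censoring or tiny libraries fall
  back to simple scaling (with a warning).
* Coverage normalization biases hotspot ratios downward when hotspots are
  large relative to their matrix (see above); rectangle choice is the
  user's responsibility.
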