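---
title: "Methods: differential chromatin accessibility with atacdiff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential chromatin accessibility with atacdiff}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and motivation

`atacdiff` reproduces, as reusable and tested code, a two-condition ATAC-seq
comparison workflow built for a setting that is common in developmental
hematopoiesis and awkward for standard count-based tools: one condition
(here, mutant erythroblasts sorted from anemic embryos) yields so few cells
(~1,000 per replicate) that replicate-level count modeling is hopeless,
while the control condition is sequenced from ~25-fold more material. The
workflow therefore aggregates replicates, calls accessible regions per
condition, and ranks regions by a depth-normalized log2-ratio sum score
rather than fitting a dispersion model. Everything downstream — genomic
feature distribution, gene linking, co-location with repressive chromatin
(H3K27me3) and transcription-factor occupancy, and gene-set overlap — is
driven by interval algebra with any-overlap (>= 1 bp) semantics.

# The model and its stages

## Insertion pileup

Each sequenced fragment contributes its Tn5 cut site: the 5' end of the
fragment (`start` on `+`, `end - 1` on `-`, 0-based). A cut at position $t$
adds coverage over $[t + s, t + s + e)$ with shift $s = -100$ and extension
$e = 200$ by default, i.e. a 200-bp window centred on the insertion — the
standard ATAC smoothing that converts point events into an interpretable
accessibility signal. Coverage is accumulated on a fixed 50-bp bin grid as
covered bases per bin divided by bin width, so one unclipped cut adds
$e / \mathrm{binsize}$ units of signal in total and pileup mass is conserved
exactly (a property the tests assert).

## Peak and domain calling

Accessible regions are detected by a Poisson local-background test in
no-control mode. For a bin with count $k$,

$$ p = P\{ \mathrm{Poisson}(\lambda_{\text{local}}) \ge k \}, \qquad
   \lambda_{\text{local}} = \max(\lambda_{\text{genome}},
   \lambda_{\text{10 kb}}), $$

where $\lambda_{\text{genome}}$ is the mean bin count over the effective
genome (total length minus excluded chromosomes and blacklist bases) and
$\lambda_{\text{10 kb}}$ is the running mean over a 10-kb window. Two
background scales, rather than a larger ladder, are used because the local
background of a desk-scale simulation has no replication structure to
justify more; the window width is configurable. Fractional bin counts
(which arise from partially overlapping smoothing windows) are handled as
$P(X \ge k) = P(X > \lceil k \rceil - 1)$, which can only make the test
conservative. Benjamini–Hochberg q-values are computed jointly over all
bins of the genome; runs of bins with $q \le 0.05$ become peaks, annotated
with a summit (centre of the leftmost maximal bin), minimal p and q, and
fold enrichment over the local background.

Broad domains (for repressive marks such as H3K27me3) use the two-tier
broad-cutoff rule: candidate runs are maximal stretches of bins significant
at the weak cutoff (0.1); a run survives only if it contains at least one
bin significant at the strong cutoff (0.05); surviving runs are linked
across gaps of up to four bins (configurable). A matched input library,
when available, replaces the treatment track in the background estimate
after scaling to the treatment total.

## The differential score

Both condition tracks are scaled to signal-per-million, and a genome-wide
binned log2 ratio is formed with a pseudocount $\psi$:

$$ r_i = \log_2 \frac{m_i + \psi}{c_i + \psi}. $$

Each accessible region of the *test-condition* peak set receives the sum of
$r_i$ over every bin it overlaps by at least one base — deliberately the
`bedtools map -o sum` convention, with no pro-rating of partially
overlapped bins, because that is the operation the original workflow names.
Regions with score $\ge \tau = 15$ are reported as "more accessible" in the
test condition, ranked by score. The threshold is an empirical constant of
the reproduced workflow, carried as a visible parameter rather than an
FDR-calibrated quantity; the negative tail is computed but not thresholded
by default, because lower accessibility in the low-input condition is
confounded with assay sensitivity. Regions present only in the
test-condition peak set (zero overlap with the reference set, half-open
semantics) are reported separately as condition-exclusive.

Scoring only the test-condition peak set mirrors the reproduced analysis;
scoring any other region set is a one-line change since
`region_sum_scores()` takes an arbitrary `GRanges`.

## Annotation and integration

Feature classification is CEAS-style with a fixed priority — promoter >
5'UTR > 3'UTR > exon > intron > distal intergenic — where the promoter is
the TSS ± 1 kb by default (the workflow never states its window; ±1 kb is
the common convention and it is configurable). UTRs require CDS
coordinates; BED6 genes contribute exon/intron only. The whole-genome
baseline classifies every base by the same priority, so both the region
and baseline columns of the distribution table sum to one and the baseline
is testable against a per-base oracle.

Gene linking extends each region by $w = 10$ kb on both sides and takes
any-overlap with transcript spans; extending regions or genes is provably
equivalent and the tests check this on random instances. DE co-location
intersects linked genes with a user-supplied differential-expression table;
mark/TF co-location is any-overlap against called domains or peaks, with
overlapping base counts reported. Gene-set overlap uses the exact
hypergeometric upper tail

$$ p = P(X \ge k), \quad X \sim
   \mathrm{Hypergeom}(|U|,\, |B|,\, |A|), $$

with the gene-model universe as the default background (the database-backed
enrichment tools used in the original analysis have an unknowable
background; user-supplied GMT libraries replace them here). Heat-map
matrices average track signal over equal windows around region midpoints
(or over the rescaled region body), rows ordered by descending score.

# The synthetic-data generator

The generator emulates the study design rather than sequence-level
realism: a deterministic toy genome (2 chromosomes x 1 Mb, 200
non-overlapping genes with exon/intron/CDS structure on both strands),
planted accessible regions in three active categories — `shared` (equal in
both conditions), `mutant_only` (open only in the test condition) and
`fold_changed` (open in both, stronger in the test condition) — plus broad
repressive-mark domains over half of the fold-changed regions, point-source
TF sites, and a matched DE table with a "multilineage"-style signature
constructed to overlap the DE genes at an expected 30%.

Cut sites are homogeneous Poisson: background 0.002 cuts/bp, multiplied by
22 inside planted accessible regions and additionally by $2^{\delta}$
($\delta = 3$) in the test condition for fold-changed regions. These
constants were calibrated once, analytically and on held-out seeds, so
that the planted truth is decisive rather than marginal at the default
scale: a 22-fold peak leaves ~15-20 expected cuts per region, enough that
region detection does not ride the significance boundary, and $\delta = 3$
compensates for the attenuation that per-million normalization introduces
on a 2-Mb genome, where the planted signal is a non-trivial share of the
total library (on a real genome this attenuation is negligible; on a toy
genome it subtracts several log2 units from a region's sum score).
Planted regions are kept >= 8 kb apart so that no region sits inside
another's 10-kb local-background window — each planted region is an
independent detection problem. ChIP libraries are simulated at 5x the ATAC
depth, reflecting that ChIPmentation input here comes from 100k-500k cells
rather than ~1,000.

Depths are symmetric by default; `depth_mutant = 1/25` reproduces the
~1,000- vs ~25,000-cell asymmetry. The depth-asymmetry validation instead
simulates one deep library over planted regions of mixed strength (a
strong 22x set pooled with a weak 6x set) and subsamples it 1/25: the
subsample calls fewer peaks, and the peaks it does call lie almost
entirely within the full-depth set — the qualitative behaviour of the
original mutant-vs-control comparison, where 92% of low-input peaks were
contained in the deep peak set. A mixture is required because a simulation
containing only decisively strong peaks loses nothing at 1/25 depth.

What the generator does *not* model: Tn5 sequence bias, nucleosomal
fragment-length structure, GC bias, replicate-level biological variance,
and chromatin-state autocorrelation. Passing tests on this fixture
demonstrate correctness of the computations and calibration of the
statistics under Poisson sampling — not robustness to the biases of real
libraries.

# Numerical choices and edge cases

* All file formats are 0-based half-open; in memory the package uses
  `GRanges`. Bookended intervals never overlap; merging treats a gap of
  zero as mergeable.
* Chromosome names are compared exactly (no `chr` aliasing); an unknown
  chromosome is an error, not a silent drop.
* Summit ties break leftmost; output ordering is by (chromosome, start,
  end, name) everywhere, so runs are bit-reproducible.
* $\psi = 1$ is applied after per-million scaling (the common
  coverage-comparison default); zero-signal tracks are an error rather
  than a NaN factory.
* p-values are floored at the smallest positive double; BH is
  `stats::p.adjust`.
* The blacklist is applied twice — to reads before pileup and to called
  peaks — and both removals are logged.
* Degenerate inputs (empty read sets, empty peak sets, regions beyond
  chromosome ends) return empty results or clip explicitly; only
  contradictory inputs (start >= end, overlapping bedGraph records) raise
  errors.

# Problem sizes used in validation

The test suite validates interval algebra and scoring against per-base and
brute-force oracles (1,000 and 500 random instances), calibrates the
caller's null on five seeds of a 100,000-bin homogeneous Poisson genome,
and runs the full pipeline on the default 2-Mb fixture; these sizes give
stable statistics while keeping a full run in minutes on one core. The
same fixture underlies `scripts/acceptance.R`, which recomputes every
headline quantity from scratch.

# Known limitations

* The score threshold $\tau$ is empirical; no FDR is attached to region
  scores, by design of the reproduced workflow.
* No replicate-aware testing: aggregation is the intended operating mode.
* The two-scale local background is a simplification of multi-scale
  lambda laddering; with very non-uniform real backgrounds a finer ladder
  may behave differently.
* One-directional overlap percentages are reported in both directions,
  but the headline figure follows the test-in-reference direction.
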