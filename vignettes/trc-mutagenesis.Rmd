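---
title: "Calling directional transcription-replication conflicts and quantifying R-loop mutagenesis"
author: "trcscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling directional transcription-replication conflicts and quantifying R-loop mutagenesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trcscape)
```

## The analysis in one paragraph

Replication forks and transcription machinery collide. When an R-loop —
a co-transcriptional DNA:RNA hybrid — sits in the fork's path, the
orientation of the encounter matters: *head-on* conflicts (fork and
transcription converging) are markedly more genotoxic than
*co-directional* ones. `trcscape` implements the full computational
path around this observation: orient each stranded R-loop peak against
the local replication fork directionality (RFD) from OK-seq, screen
chromatin and DNA-damage-response factor coverage for center-versus-
flank enrichment at the resulting TRC sites, and quantify somatic
mutagenesis conditioned on conflict orientation — mutation density and
hotspots, per-tumor R-loop mutation burden by chromatin-remodeler
status, SBS96/ID83 mutational signatures extracted by Kullback-Leibler
NMF, per-mutation signature assignment, and region-conditioned risk
ratios. A seeded synthetic-genome generator with planted effects makes
every stage testable by parameter recovery, with no external download.

## Orienting conflicts

RFD is computed per genomic bin from strand-resolved Okazaki-fragment
counts as $\mathrm{RFD} = (R - L)/(R + L) \in [-1, 1]$, where $+1$
means every fork in the population moves rightward. A stranded R-loop
peak becomes a TRC site when the length-weighted mean RFD over the peak
satisfies $|\overline{\mathrm{RFD}}| > 0.75$ — i.e. replication
direction is essentially homogeneous across the cell population there.
The orientation rule is:

* fork rightward ($\overline{\mathrm{RFD}} > 0$) over a minus-strand
  peak, or fork leftward over a plus-strand peak → **head-on**;
* otherwise → **co-directional**.

Two numerical choices deserve mention. The threshold is read as
strictly greater than 0.75 (a `strict = FALSE` switch admits equality;
boundary sites are vanishingly rare in practice). And because the
source data do not state a coverage requirement, peaks whose RFD track
covers less than `min_covered_fraction` (default 0.5) of their length
get a missing mean and are excluded rather than scored from a sliver of
signal. Two exact symmetries pin the semantics down and are enforced by
property tests: flipping every peak strand swaps the orientation labels
exactly, as does negating the RFD track.

## The factor screen

For each factor coverage track, signal is averaged over ±10 kb around
each TRC midpoint and compared against two 20 kb flank windows centered
1 Mb upstream and downstream of the site (window sizes chosen at the
scale of megabase DNA-damage domains). Windows are oriented: for a
leftward-moving fork, upstream lies to the right. The score per flank
is a log2 ratio,

$$\mathrm{RMS}_{up} = \log_2 \frac{\text{center mean}}{\text{upstream
flank mean}},$$

and a factor is *enriched* when both scores exceed 0.25, *depleted*
when both fall below −0.25. The score is computed on pooled per-site
window means (mean across sites, robust to site-count imbalance; a
median variant is exposed via `stat = "median"`). Tracks are treated as
non-negative coverage and not renormalized first — a log-ratio is
scale-invariant, so depth differences between tracks cancel. Factors
whose flank mean is zero are flagged unscorable rather than given an
infinite score.

Whether profiles should be oriented by fork direction or by
transcription direction is analysis-dependent; both are provided
(`orient_by`), and nothing defaults silently to one when the site frame
lacks the needed column. Set-level enrichment over a ranked factor list
uses the weighted Kolmogorov-Smirnov running sum (hit increments
proportional to $|m|^p$, $p = 1$; miss decrements $1/(N - N_h)$), with
an add-one-corrected label-permutation p-value (1000 permutations,
seeded). Chromatin contact maps are aggregated as oriented ±2 Mb
submatrices around sites (10 kb bins), rotated 180° for leftward forks
so that upstream is always top-left.

## Mutation analysis

Mutation catalogs use a flat COSMIC-like TSV (sample, chrom, 1-based
pos, ref, alt, functional class, gene); positions are converted to
0-based half-open coordinates once, on read. A mutation colocalizes
with an interval iff its start offset lies inside it — one unambiguous
rule, also for deletions.

Hotspots are called from per-kb density tracks with two-threshold
broad-peak semantics: maximal runs of bins at or above `c_peak`
(default 0.25), neighbouring runs merged when the gap is at most
`max_gap` with all intervening bins at or above `c_link`, short regions
discarded. The linking cutoff, minimum length (200 bp) and maximum gap
(500 bp) are configurable defaults in the spirit of broad-peak callers;
only the primary cutoff is fixed by the analysis design. The caller is
verified against an exhaustive per-bin scan oracle on thousands of
random tracks.

Per-tumor R-loop burden counts a tumor's mutations inside the *union*
of R-loop peaks (so splitting a peak changes nothing), keeping only
tumors with at least 1000 mutations. Tumors are *deficient* for a
chromatin gene when they carry a frameshift, missense or nonsense
mutation inside it. Burden groups are compared with a two-tailed
Wilcoxon rank-sum test — implemented in the package because the exact
small-sample branch must handle ties (full enumeration when both groups
have ≤ 10 tumors; tie-corrected normal approximation with continuity
correction otherwise), which `stats::wilcox.test` declines to do
exactly. Orientation contrasts of per-site mutation rates (fractions of
sites above 1 SNV/kb, 0.1 del/kb, 0.1 ins/kb) use a one-tailed Fisher
exact test for head-on excess; hotspot-gene-class association uses
pairwise 2×2 chi-square with Yates' continuity correction plus an
overall uncorrected r×c test. The within-gene shuffling control
re-places each R-loop interval uniformly inside its host gene,
preserving length.

## Mutational signatures

SBS96 channels are pyrimidine-centric trinucleotide substitution
classes; purine-centered records are reverse-complemented on
classification, so complementing an entire catalog leaves the count
matrix invariant (a property test). ID83 follows the canonical indel
classification: 1-bp events by base and homopolymer run length, longer
events by adjacent tandem-repeat copies, repeat-free deletions by
microhomology length, all after left-alignment. The classifier is
cross-checked against an independent plain re-implementation on random
indels.

Extraction factorizes the channels×samples count matrix $V \approx WH$
by multiplicative Kullback-Leibler updates — the Poisson-likelihood
choice for count data — with a small pseudocount for numerical safety,
column-normalized signatures, and best-of-`n_restarts` (default 20)
selection by final divergence. The KL objective is non-increasing per
iteration by construction, and the test suite asserts it on every run.
Rank selection clusters the pooled restart signatures (average linkage,
cosine distance) and requires both a mean silhouette ≥ 0.8 and
*balanced* clusters — exactly one solution per restart in each cluster
— choosing the largest qualifying k; the balance requirement is what
prevents a clean rank-k dataset from being scored rank-k+1 by a
consistently-shaped noise component.

Per-sample exposures are refit against fixed signatures (H-only
updates), giving per-(sample, channel) posteriors
$p(s \mid c) = W_{cs}h_s / \sum_{s'} W_{cs'}h_{s'}$; each mutation is
then assigned a generating signature by an independent seeded
categorical draw (an `expectation` mode returns the argmax
deterministically for variance-free pipelines). Counts of assigned
mutations per signature in region sets (all R-loops, head-on,
co-directional) feed risk ratios with 95% Wald intervals,
continuity-corrected (+0.5) only when a zero count forces it, and
flagged when so. Factor-conditioned signature spectra are computed on
the intersection of ±2.5 kb-padded R-loops with each factor's peaks,
expressed as log2 fold-change against all padded R-loops, and clustered
with average linkage on 1 − Pearson distance into 7 clusters by
default; constant rows, whose correlation is undefined, become reported
singletons.

## What the synthetic generator emulates — and what it does not

`simulation_config()` fixes every planted parameter; the same
configuration yields byte-identical files. The model:

* **Genome**: i.i.d. bases with separate GC content inside and outside
  gene bodies. Real genomes have repeats, CpG depletion and isochores;
  nothing here tests mappability- or repeat-driven artifacts.
* **Genes**: placed in non-overlapping slots, log-normal lengths,
  random strand; a configurable fraction silenced, log-normal
  expression otherwise.
* **Replication**: origins at exponential spacings (mean
  `origin_spacing`, default 150 kb); RFD is +1/−1 plateaus with a
  linear ramp of width `terminus_width` (default 30 kb) across each
  inter-origin midpoint. Localized termination zones match the OK-seq
  picture; a genome-wide gradient would leave too little homogeneous
  territory for any orientation analysis.
* **R-loops**: per gene, probability
  $p = p_{max} \cdot e/(e + h)$ monotone in expression $e$
  (defaults $p_{max} = 0.9$, half-saturation 2); width log-normal with
  1 kb median, placed uniformly in the gene body, strand equal to the
  gene strand. These are fixture choices, not claims about DRIPc peak
  geometry.
* **Factor tracks**: multiplicative log-normal noise around a flank
  level, with the mean multiplied by `center_fold` within ±10 kb of
  each site and additionally by `orientation_bias` at head-on sites.
* **Tumors**: fixed mutations per tumor; per-tumor signature exposures
  drawn from a Dirichlet around the base mixture (concentration 0.7).
  The heterogeneity is not cosmetic: with identical exposures the
  count matrix is rank 1 and no factorization could separate the
  signatures, and real catalogs show strong per-tumor variability.
  Each mutation draws a signature, then a channel, then a region class
  with probability proportional to class length times planted
  multipliers (`ho_rate_multiplier`, per signature if a vector;
  `burden_multiplier` inside R-loops for deficient tumors), then a
  uniformly chosen position whose reference context matches the
  channel. Deficient tumors receive one disrupting mutation in the
  target gene before burden sampling, so status is independent of
  burden noise. Generated indels are restricted to 1-bp channels; the
  ID83 classifier itself covers all 83.
* **Contacts**: power-law decay $(|i - j| + 1)^{-\alpha}$ at 10 kb
  bins; contacts among the bins 0.2–1 Mb upstream (fork-wise) of each
  head-on site are multiplied by `upstream_compaction_fold`. The
  compaction is local to each site's own upstream block, which is what
  makes a head-on versus co-directional aggregate contrast meaningful.

Passing recovery tests on this generator shows the *estimators* are
correct and unbiased at realistic effect sizes; it does not show
robustness to alignment artifacts, copy-number structure, or the
kilobase-scale covariation of real chromatin data.

## Problem sizes and test design

The test-suite study systems are sized for a laptop-class run: screens
use 500 sites spaced 150 kb on a virtual ~76 Mb chromosome (spacing
keeps planted ±10 kb zones from contaminating the ±1 Mb flanks of
neighbouring sites); mutation analyses use 2 × 8 Mb genomes with
~2000 genes and 16–100 tumors of 800–2000 mutations; signature recovery
uses 100 tumors × 2000 mutations with four peaked, disjoint planted
signatures (≈5 dominant channels each — the realistic shape, and the
per-channel depth KL-NMF needs at this sample size). The end-to-end
demo (`run_demo()`) runs a deliberately small 2 × 3 Mb system in
seconds and writes a byte-reproducible metrics file. Statistical
recovery assertions use 3-standard-error bands around planted values;
exact algorithmic assertions (hotspot caller, enrichment-score walk,
Fisher/Wilcoxon/chi-square, coverage resampling) are checked against
independent brute-force oracles on ≥ 1000 seeded random instances.

## Known limitations

* The screen's flank windows can overlap neighbouring sites' planted
  zones when sites are dense; on real data this is a biological fact
  (hit regions cluster), and on synthetic data the spaced-site layout
  quantifies the estimator without that contamination.
* The RMS is a fixed-window ratio, not a peak-shape model; factors
  with sharp sub-kilobase peaks and broad depleted shoulders can score
  as `none`.
* Signature assignment is a single categorical draw per mutation, as
  the analysis design dictates; for small region sets the induced
  assignment noise dominates, and the `expectation` mode exists for
  variance-free comparisons.
* The generator's placement engine matches mutational contexts
  exactly but ignores replication timing, expression-coupled repair
  and strand asymmetries; transcription-strand-biased signature
  classes (SBS192) are out of scope.

## A minimal session

```{r, eval = FALSE}
cfg <- simulation_config(seed = 1)
bundle <- simulate_genome(cfg, "bundle_dir")
trcs <- call_trcs(bundle$rloops, bundle$rfd, trc_params())
table(trcs$orientation)

screen <- screen_factors(trcs, bundle$factor_tracks, screen_params())
subset(screen, klass != "none")

run_demo("demo_out", seed = 1)
```
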