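# trcscape

Directional transcription–replication conflict (TRC) analysis from
R-loop maps and replication fork directionality, with downstream
quantification of cancer mutagenesis.

## The problem

Replication forks collide with transcribed, R-loop-forming loci in one
of two orientations — **head-on** (converging) or **co-directional** —
and head-on encounters are the genotoxic ones. Given (i) stranded
R-loop peaks (DRIPc-seq; peak strand reports transcription direction)
and (ii) replication fork directionality from OK-seq,

$$\mathrm{RFD} = \frac{R - L}{R + L} \in [-1, 1],$$

a peak with homogeneous fork direction ($|\overline{\mathrm{RFD}}| >
0.75$ over the peak) is a directional TRC site, head-on when the fork
sign opposes the peak strand. Around those sites the package:

* screens factor coverage tracks by the center-versus-flank
  **Rank Metric Score** — mean signal over ±10 kb versus 20 kb windows
  at ±1 Mb, $\mathrm{RMS} = \log_2(\text{center}/\text{flank})$, hit
  when both scores pass ±0.25 — plus weighted-KS set enrichment,
  oriented metaprofiles/metagenes and ±2 Mb Hi-C aggregates;
* quantifies mutagenesis by orientation: per-kb mutation density
  tracks, two-threshold hotspot calling (0.25 primary cutoff),
  per-site SNV/indel rates with one-tailed Fisher contrasts, and
  per-tumor R-loop mutation burden (tumors ≥ 1000 mutations) compared
  between chromatin-remodeler-proficient and -deficient tumors
  (frameshift/missense/nonsense rule) by two-tailed Wilcoxon;
* extracts mutational signatures from SBS96/ID83 context matrices by
  Kullback–Leibler NMF ($V \approx WH$, multiplicative updates, best
  of 20 restarts), refits per-sample exposures, assigns each mutation
  a signature by a seeded multinomial draw, and compares signature
  activity across region classes as risk ratios with 95% Wald
  intervals and factor-conditioned log2 fold-change clusters.

A fully seeded synthetic-genome generator (`simulate_genome()`) plants
every effect the pipeline is supposed to detect — fork-direction
ramps, factor enrichment folds, orientation biases, signature
mixtures, burden multipliers, upstream chromatin compaction — so each
stage has a parameter-recovery test with no external data.

## A worked example

```r
library(trcscape)

cfg <- simulation_config(seed = 1,
                         chrom_lengths = c(chrA = 3e6, chrB = 3e6),
                         n_genes = 120, edge_margin = 1.05e6)
bundle <- simulate_genome(cfg)
trcs <- call_trcs(bundle$rloops, bundle$rfd, trc_params())
table(trcs$orientation)
#> codirectional       head_on
#>            23            22

screen_factor(trcs,
              simulate_factor_track(trcs,
                list(center_fold = 1.5, flank_level = 1, noise_cv = 0.1),
                cfg$chrom_lengths, 1000, seed = 2),
              screen_params(flank_offset = 3e5, window_halfwidth = 3e5),
              factor_name = "example")[, 1:4]
#>    factor    rms_up rms_down    klass
#> 1 example 0.5034548 0.484717 enriched
```

Of 54 simulated R-loop peaks, 45 pass the |RFD| > 0.75 filter and
split almost evenly by orientation (the generator plants no
orientation bias). A factor track planted at 1.5-fold center
enrichment scores close to RMS = log2(1.5) ≈ 0.58 on both flanks —
slightly shrunk because flank windows of densely packed sites overlap
their neighbours' enriched zones — and is called a hit.

The one-command demonstration runs every stage on a small synthetic
system and writes `report.txt` plus a byte-reproducible
`metrics.json`:

```r
run_demo("demo_out", seed = 3)
```

```
trcscape demo (seed 3)
R-loop peaks: 65; TRC sites: 61 (32 head-on, 29 co-directional)
factor screen: 3 enriched, 1 depleted of 6 tracks
head-on - co-directional abundance delta: 3.657 (SE 0.678)
mutation hotspots: 96 (24.0% in R-loop-prone genes)
sites >1 SNV/kb: head-on 0.875 vs co-directional 0.276 (Fisher p = 1.85e-06)
R-loop burden medians: deficient 29.5 vs proficient 15.0 (Wilcoxon p = 3.45e-05)
signature 1 head-on/co-directional risk ratio: 1.99
```

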