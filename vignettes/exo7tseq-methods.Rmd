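---
title: "Methods: strand-specific DSB end-count analysis with exo7tseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: strand-specific DSB end-count analysis with exo7tseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exo7tseq)
```

## The measurement and the model

Meiotic recombination starts with programmed DNA double-strand breaks (DSBs)
made by SPO11, mostly at hotspots positioned by PRDM9. Each break is
resected 5'→3', leaving 3' single-stranded tails. Assays of the
Exo7/T-seq / S1-seq / END-seq family trim that single-stranded DNA away with
exonucleases, ligate adapters to the blunted ends, and sequence them:
the mapped position of a read-1 5' end therefore reports, at nucleotide
resolution, a *resection endpoint* (or, for a minority of reads, a
recombination-intermediate end near the break itself).

The signal anatomy this package assumes and analyses is:

* **top-strand** ends accumulate to the *right* of a hotspot center
  (rightward resection), **bottom-strand** ends to the *left* (leftward
  resection), each at distances of roughly 0.3–2.5 kb;
* a **central signal** of recombination-intermediate ends within tens of bp
  of the break site, on both strands;
* a roughly **uniform background** of ends from random breakage, present
  regardless of SPO11 activity.

All genomic coordinates in the package are 0-based, half-open (the
BED/bedGraph convention), stated once here and used everywhere.

## End counting

`extract_end_counts()` keeps properly paired, primary, first-in-pair
alignments with MAPQ ≥ 20 and adds one count per read at the base
immediately *outward* of the read-1 5' alignment end — the last nucleotide
the exonucleases removed. Whether the original analyses counted that base or
the 5' base itself cannot be determined to single-base precision from the
method description; the package exposes `adjacent_base = FALSE` for the
other convention. The choice shifts every position by 1 bp and is invisible
to every downstream statistic, which operates at ≥ 100 bp scales. The RPM
denominator is the number of *retained* read-1 alignments, i.e. the same
universe the counts are drawn from, so a track whose ends all fall in
bounds has an RPM sum of exactly 10^6.

## Co-oriented metaprofiles

`aggregate_around_centers()` averages signal over hotspot centers in a
window of ± 5,000 bp (default `half_width`; resection signal extends to
about 2.5 kb, so the window holds it with margin to spare). With
`co_orient = TRUE` the bottom strand is mirrored (`-d` onto `+d`) so both
resection directions superimpose on positive offsets. Two contracts were
genuinely open and are fixed as follows:

* **Mean over centers, not pooled sum.** The profile value is the mean of
  per-center sums, which makes genotypes with different catalog sizes
  comparable. (For catalogs with equal window counts the pooled-read
  alternative differs only by a constant factor and all downstream
  statistics — which are scale-free — coincide.)
* **Averaging before smoothing.** Replicates are averaged at the profile
  level after RPM scaling, then smoothed. Both operations are linear, so
  the opposite order gives identical results; one order had to be written
  down.

Smoothing uses a 151-bp Hanning (raised-cosine) window normalized to unit
sum, with *reflection* padding at the edges. Reflection rather than
zero-padding keeps constant signals exactly constant and avoids an
artificial decay over the outermost 75 bp of the profile; total signal is
conserved up to edge effects below 0.5 % at the default window sizes.
Single-locus and PAR views use the same smoother on binned data (10-bp or
40-bp bins, 51-bin window).

## Resection-length estimation

The estimator follows the canonical stage order
*aggregate → average replicates → smooth → subtract background →
normalize → histogram*:

1. **Background subtraction.** The profile value at a single far-flank
   offset (+2,500 bp) is taken as the background estimate and subtracted
   everywhere; negatives are clamped to zero. On a co-oriented profile
   there is no distinct −2,500 offset, so the single positive flank is
   used. Because the background is uniform, adding any constant to a
   profile leaves all downstream results unchanged.
2. **Peak normalization.** Division by the maximum over offsets in
   (100, 2500], so the resection-endpoint peak has height exactly 1. A
   window with no positive value raises the explicit error
   `"no resection signal to normalize"`.
3. **Length histogram.** Offsets ≤ 100 (the hotspot core and the whole
   anti-oriented side) and > 2,500 are zeroed; "positions 100 bp" is read
   as *at or below* 100 bp because the stated purpose of the step is to
   remove core-proximal signal. The remaining signal is split into 24 bins
   of 100 nt over (100, 2500] and reported as fractions of the remaining
   total.
4. **Summary mean.** No formula for "average resection length" accompanies
   the published number, so the package defines it as the fraction-weighted
   bin midpoint, `sum(fraction_i × midpoint_i)` with midpoints
   150, 250, …, 2,450 nt. The full distribution is always reported next to
   the mean so any other summary can be read off.

The distribution is computed from the smoothed profile by default;
`smooth_first = FALSE` in `resection_analysis()` allows a sensitivity check
on unsmoothed data.

## Peak calling and hotspot-usage classification

The internal caller (`call_peaks()`) is deliberately simple plumbing:
strands are combined, 1-kb windows slide at 100-bp steps, each window is
scored against a single global Poisson rate (total signal / genome length),
p-values are BH-adjusted genome-wide, and windows passing q < 0.01 are
fused. This mirrors a global-background model; fidelity to any external
caller is explicitly not promised — `import_narrowPeak()` exists to bring
in externally called peaks.

`widen_and_merge()` grows each peak by 5 kb *total* (2.5 kb per side;
`per_side = TRUE` selects the other reading of "widened by 5 kb") and
merges overlapping or book-ended intervals, keeping the maximum score.
`classify_overlap()` then labels each merged peak `prdm9_only`,
`default_only`, `both` or `neither` by ≥ 1 shared bp with each catalog;
book-ended intervals (0 shared bp) do not count.

**Quantifying usage.** The per-peak *count* fractions saturate once every
hotspot of a catalog is detectable: at high depth both catalogs are fully
recovered and the count fraction pins near the catalog-size ratio whatever
the underlying event split. `hotspot_usage()` therefore reports a
signal-weighted share: per-peak signal minus the expected background
(a robust per-bp rate — the genome-wide median of 1-kb bin counts — times
peak width, clamped at zero), summed per overlap class. This share tracks
the fraction of DSB events at each hotspot class across the full range of
planted weights, which is the quantity the genotype comparison needs. Both
statistics are reported.

## The synthetic-data generator

`simulate_dataset()` emulates the statistical structure above on a
synthetic genome so every stage runs and is testable in seconds. Design
choices, fixed once:

* **Genome.** Three 4-Mb autosomes plus a 2-Mb "X" carrying a 100-kb
  PAR-like interval near its distal end. The genome is sized so ~400
  hotspots fit at ≥ 15 kb spacing: peaks widened by 5 kb span at most
  ~11 kb, so widened peaks of neighbouring hotspots cannot merge across
  categories, which would otherwise flood the classification with `both`
  labels an analyst would never accept in a designed benchmark.
* **Catalog.** ~200 PRDM9-directed and ~200 default hotspots on a jittered
  grid, heats drawn once per catalog from an exponential distribution and
  stored, so all genotypes share hotspot identities, as in a real design;
  5 PRDM9 hotspots are planted inside the PAR.
* **Event sampling.** A category (PRDM9 vs default) is drawn first with the
  configured weights, then a hotspot within the category proportional to
  heat × PAR boost. Sampling in two stages makes the configured
  `default_weight` the *exact* expected event fraction at default hotspots
  even when `par_boost ≠ 1`, which is what the recovery analyses compare
  against.
* **Resection lengths.** `resection_min + Gamma(mean − min, sd)` — a
  smooth, unimodal, right-skewed distribution with a hard minimum
  (default 300 nt) and expectation exactly `resection_mean`. The published
  work plots distributions but states no parametric form; the shifted
  Gamma is the simplest shape consistent with them.
* **DSB positions** are Normal(center, 50 bp), approximating the width of
  break-position clusters within a hotspot; **central signal** is uniform
  within ± 50 bp of the break. The width and fraction of the central
  signal are free parameters of the generator (the real shape of
  recombination-intermediate ends is not characterized here); the default
  `central_fraction = 0.15` places a minority of reads centrally, and the
  core-exclusion step of the resection estimator removes nearly all of it.
* **Background and library composition.** Background is Poisson-uniform at
  0.02 reads/bp for *every* preset, independent of DSB events. A real
  library is sequenced to a depth unrelated to DSB yield, so a Spo11-null
  control produces a full-size, background-only library; holding the
  background rate constant reproduces that: the control's PAR signal
  density (in RPM) is then comparable to a DSB-proficient mutant that has
  merely lost PAR activity, rather than vanishing by normalization.
  The default libraries are therefore deliberately background-rich
  (~58 % background reads).
* **Determinism.** Replicate `r` draws at `seed + r − 1`; identical inputs
  and seed give bit-identical tracks, and events whose end falls outside a
  chromosome are discarded from both the track and the truth record so the
  two always reconcile exactly.

### Genotype presets

| preset | events | default weight | PAR boost | resection mean (nt) |
|---|---|---|---|---|
| `wildtype` | 2×10^5 | 0.05 | 16 | 950 |
| `ankrd31_EA` | 2×10^5 | 0.06 | 16 | 950 |
| `ankrd31_EA_over_null` | 2×10^5 | 0.15 | 16 | 950 |
| `ankrd31_dC` | 2×10^5 | 0.35 | 0 | 850 |
| `ankrd31_null` | 2×10^5 | 0.35 | 0 | 850 |
| `spo11_null` | 0 | — | — | — |

These encode the qualitative contrasts the analysis is designed to detect:
elevated default-hotspot usage and ~100 nt shorter resection in the null
and ΔC genotypes, near-wild-type behaviour of the EA allele, PAR signal
loss in null/ΔC, and a background-only Spo11-null control. The numbers
(2×10^5 events, mean 950 / sd 300 nt, boost 16 over 5 PAR hotspots) were
chosen once as a desk-scale design in which each contrast is comfortably
resolvable: the mean-resection standard error is a few nt, the PAR holds
roughly a quarter of wild-type DSBs, and all four genotype comparisons run
in well under a minute each.

### What the generator does *not* emulate

Mappability and alignability structure, PCR duplicates, sequencing error,
chromatin-driven heterogeneity of background, per-hotspot resection
heterogeneity, and the detailed shape of recombination-intermediate ends.
Passing recovery tests on this generator shows the *estimators* are
correct and unbiased under the stated model; it does not certify behaviour
on real libraries where those nuisances exist.

## Numerical and degenerate-input conventions

* Smoothing requires an odd window no longer than the signal; window
  length 1 is the identity.
* `to_rpm()` refuses to normalize twice and requires a positive
  denominator.
* An all-zero resection window is an error, not a silent zero; the
  pipeline additionally marks a genotype *background-only* when its
  smoothed profile rises less than 2-fold over the far-flank background
  (`min_enrichment`), which is how a noisy but DSB-free control is
  distinguished from a hard error.
* Peak/catalog ties at shared boundaries count as no overlap; merged-peak
  scores are maxima, not sums.
* The Poisson caller operates on raw integer counts only.

## Pipeline problem sizes

`run_pipeline()` on the default design (14-Mb genome, ~400 hotspots, two
replicates of 2×10^5 events plus 2.8×10^5 background reads per genotype)
takes a few seconds per genotype; the test suite and the acceptance script
use the same design, with some unit tests on a 2.5-Mb three-chromosome
miniature for speed. Reruns with the same configuration are byte-identical,
and the run manifest records the package version, seed, parameters and
output digests.
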