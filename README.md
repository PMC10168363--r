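# exo7tseq

Downstream analysis of strand-specific, nucleotide-resolution maps of
meiotic DNA double-strand-break (DSB) ends, as produced by assays of the
Exo7/T-seq / S1-seq / END-seq family. In these assays, exonucleases remove
the single-stranded DNA at resected DSBs and sequencing adapters are
ligated to the blunted ends, so mapped read-1 5' ends report **resection
endpoints**: top-strand ends accumulate to the right of a DSB hotspot
center (rightward 5'→3' resection), bottom-strand ends to the left, with a
central signal from recombination intermediates riding on a uniform
background.

The package is aimed at analysts comparing genotypes (e.g. wild type vs
*Ankrd31* or *Spo11* mutants) and provides:

* **End counting** — `extract_end_counts()` turns mapped paired-end
  alignments (BAM) into per-base, per-strand end-count tracks (one count at
  the base immediately outward of each retained read-1 5' end; MAPQ ≥ 20,
  primary, properly paired), with RPM scaling and lossless
  bedGraph-pair import/export.
* **Co-oriented metaprofiles** — `aggregate_around_centers()` averages
  signal in ±5 kb windows around hotspot centers, flipping the bottom
  strand so both resection directions superimpose
  (value at offset *d* = mean over centers of top[*c*+*d*] +
  bottom[*c*−*d*]), followed by 151-bp Hanning smoothing with reflection
  padding.
* **Resection-length estimation** — background subtraction (profile value
  at +2,500 bp), normalization to the resection-endpoint peak maximum over
  (100, 2500], and the resection-length distribution: fractions of
  remaining signal in 24 × 100-nt bins over (100, 2500], summarized by the
  fraction-weighted bin-midpoint mean
  `L̄ = Σᵢ fᵢ·midᵢ`.
* **Peak classification** — a global-Poisson sliding-window caller (or
  `import_narrowPeak()`), 5-kb widen-and-merge, and classification of each
  merged peak against PRDM9-directed and default hotspot catalogs by ≥ 1 bp
  overlap, plus a background-corrected signal-share statistic of
  default-hotspot usage and PAR-interval signal quantification.
* **A synthetic-data generator** — `simulate_dataset()` with genotype
  presets (wild type, *Ankrd31* mutant series, *Spo11* null) emulating
  strand-asymmetric resection endpoints (shifted-Gamma lengths), central
  signal, uniform background, replicate structure and per-genotype effects
  (default-hotspot activation, PAR signal loss, ~100 nt resection
  shortening), with a full truth record for parameter-recovery testing.

## Worked example

Simulate a wild-type and an *Ankrd31*-null dataset on the default synthetic
design (14-Mb genome, ~200 PRDM9 + ~200 default hotspots, 2 replicates of
2×10⁵ DSB events each), then run the analysis:

```r
library(exo7tseq)

genome  <- default_genome()
catalog <- simulate_hotspot_catalog(genome, seed = 1)
prdm9   <- catalog[catalog$category == "prdm9", ]

wt  <- simulate_dataset(genome, catalog, make_genotype_preset("wildtype",     seed = 1))
mut <- simulate_dataset(genome, catalog, make_genotype_preset("ankrd31_null", seed = 2))

res_wt  <- resection_analysis(wt$counts,  prdm9, genotype = "wildtype")
res_mut <- resection_analysis(mut$counts, prdm9, genotype = "ankrd31_null")
res_wt$distribution
#> ResectionDistribution [wildtype] : 24 bins over ( 100 , 2500 ] nt
#>   mean resection length: 939.3 nt
res_mut$distribution
#> ResectionDistribution [ankrd31_null] : 24 bins over ( 100 , 2500 ] nt
#>   mean resection length: 842.6 nt
compare_resection(res_wt$distribution, res_mut$distribution)$shift_nt
#> [1] 96.7
```

The estimated means sit within ~10 nt of the configured 950/850 nt (the
small downward bias comes from truncating the distribution at 2.5 kb and
residual central signal), and the recovered genotype shift of 96.7 nt
matches the planted 100-nt resection shortening. Peak classification on the
mutant shows the activated default hotspots:

```r
pooled <- pool_counts(mut$counts)
peaks  <- widen_and_merge(call_peaks(pooled), widen_bp = 5000, genome = genome)
ov     <- classify_overlap(peaks, prdm9, catalog[catalog$category == "default", ])
ov
#> OverlapSummary: 345 peaks
#>              count fraction
#> prdm9_only     175   0.5072
#> default_only   170   0.4928
#> both             0   0.0000
#> neither          0   0.0000
hotspot_usage(pooled, ov)$default_associated
#> [1] 0.346
```

The signal share of default-associated peaks (0.346) recovers the preset's
planted default event weight (0.35); the raw peak-count fraction (0.49)
instead reflects how many default hotspots became detectable at all. PAR
signal collapses in the mutant as designed:

```r
mean(sapply(wt$counts,  function(x) interval_signal(to_rpm(x), genome$par)$total))
#> [1] 78742
mean(sapply(mut$counts, function(x) interval_signal(to_rpm(x), genome$par)$total))
#> [1] 4058
```

`run_pipeline()` wires these stages together from a YAML/list configuration
(per-genotype TSV/BED outputs, a Markdown report, and a deterministic run
manifest); see `?run_pipeline` and the methods vignette
(`vignettes/exo7tseq-methods.Rmd`) for the model, parameter defaults and
design decisions.

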