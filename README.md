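# mirsat

Simulation and depth-aware analysis of small RNA sequencing libraries.

Small RNA-seq quantifies mature miRNAs (~22 nt) by ligating a 3' adapter,
sequencing ~50 cycles, clipping the adapter, and assigning the surviving
reads to a mature-miRNA catalogue with a one-SNV tolerance. Anyone planning
such an experiment faces three quantitative questions that this package
lets you study end to end on fully seeded synthetic data with per-read
ground truth:

* **Library composition** — what share of usable (post-clipped) reads is
  mature miRNA versus structured ncRNA, repeats, adapter dimers and
  unclassified sequence? Tissue libraries run near 68% mature-mapped;
  low-input plasma near 21%.
* **Depth of coverage** — how many new miRNAs does each added million reads
  detect (saturation), and how well does a shallow subsample's profile
  rank-correlate with the full-depth profile (adequacy)?
* **Differential expression** — with two groups of 9 replicates, does a
  negative-binomial exact test with TMM (or median-of-ratios)
  normalization and Benjamini–Hochberg FDR control recover injected fold
  changes without flagging null miRNAs?

It is aimed at bioinformaticians benchmarking small RNA pipelines and at
methods teaching: every stage (simulator, preprocessor, quantifier,
resampler, tester) is a documented R function validated against independent
oracles.

## The models in brief

* **Generator**: reads are `insert + adapter + padding` truncated to 50
  cycles; category fractions follow a composition profile; miRNA abundances
  are log-normal (sigma 3); miRNA reads carry 3' isomiR edits and one-SNV
  errors at configurable rates; a ledger records every read's truth.
* **Quantifier**: 5'-anchored matching with at most 1 substitution over the
  overlap and a ±2-nt 3' window; out-of-tolerance isomiRs go to a separate
  "others" ledger; multi-mapping reads are split uniformly or by EM;
  `RPM = count / mapped_total × 10^6`.
* **Resampling**: read-level sampling without replacement (multivariate
  hypergeometric), nested across depths; detection thresholds
  {1, 3, 5, 10, 50}; Spearman correlation of subsample vs full profile.
* **Testing**: per-gene conditional NB exact test at common dispersion φ
  (`var = μ + φμ²`; binomial when φ = 0), moment-estimated φ, BH at 0.05.

See `vignettes/mirsat-methods.Rmd` for assumptions, parameter defaults and
design decisions.

## Worked example

```r
library(mirsat)

ref     <- build_reference(300, seed = derive_seed(20260922, 1))
decoys  <- decoy_pools(ref, seed = derive_seed(20260922, 2))
profile <- simulate_abundances(ref, seed = derive_seed(20260922, 3))

lib <- simulate_library(ref, profile, composition_muscle(),
                        sim_config(200000, seed = derive_seed(20260922, 11)),
                        decoys)
pre <- preprocess_reads(lib$reads)
q   <- quantify_sample(pre$collapsed, ref, decoys)

c(initial = nrow(lib$reads), post_clipped = pre$report$n_retained,
  mapped = q$library_size)
#>      initial post_clipped       mapped
#>       200000       190036       128958

round(100 * q$composition$fractions, 2)
#>       mature        ncrna       repeat unclassified
#>        67.86         7.00         3.01        22.13

round(100 * q$composition$others_isomir, 2)
#> [1] 5.04
```

Reading the numbers: of 200,000 simulated muscle-like reads, 190,036
survive adapter clipping and the 18-nt filter (adapter dimers and
too-short inserts are removed), and 128,958 of those map to a mature miRNA
within one SNV — 67.9% mature-mapped, with 7.0% structured ncRNA, 3.0%
repeats, and 5.0% of reads in the out-of-tolerance isomiR "others" ledger
(inside unclassified, not counted as mapped).

The numbered scripts under `analysis/` run the full study and write tables
under `results/`:

```sh
Rscript analysis/01_simulate.R            # libraries + truth ledgers
Rscript analysis/02_preprocess_quantify.R # accounting + composition
Rscript analysis/03_saturation.R          # new detections per added million
Rscript analysis/04_correlation.R         # subsample-vs-full Spearman curve
Rscript analysis/05_diffexpr.R            # 9v9 exact-test DE + null check
```

For instance, `03_saturation.R` reports total new detections per added
million reads of `334 117 86 58 56 42` (Spearman rho of increment index vs
new detections = −1: each added million buys fewer new miRNAs), and
`04_correlation.R` shows a 100,000-read subsample already rank-correlating
at rho = 0.97 with the full 1M-read profile.

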