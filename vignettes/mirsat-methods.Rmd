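---
title: "mirsat: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mirsat: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirsat)
```

# What the package studies

Mature miRNAs are ~22-nt products of Dicer cleavage, quantified in bulk by
small RNA sequencing: a 3' adapter is ligated to every RNA, libraries are
sequenced for a fixed number of cycles (50 here), reads are adapter-clipped,
length-filtered, collapsed, and assigned to a catalogue of mature sequences
allowing a single nucleotide variant (SNV). Three practical questions shape
such experiments:

1. **Composition** - what fraction of the usable (post-clipped) reads is
   actually miRNA? Tissue libraries and low-input plasma libraries differ
   dramatically (roughly 68% vs 21% mature-mapped), with the remainder going
   to structured ncRNA (Rfam-like), repeats (RepBase-like), adapter dimers
   and unclassified sequence.
2. **Depth** - how many miRNAs does another million reads buy
   (detection saturation), and how faithfully does a shallow subsample rank
   the profile of the full library (correlation adequacy)?
3. **Differential expression** - with ~9 replicates per group, does a
   count-based negative-binomial exact test with FDR control find injected
   changes without flagging nulls?

No raw sequencing data accompanies the study conditions this package
emulates, so a fully *seeded synthetic generator with a per-read truth
ledger* is a first-class component: every downstream claim is validated
against generated data whose ground truth is known exactly.

# The synthetic-library generator

## Reference and abundances

`build_reference()` draws random mature sequences of 20-23 nt (the typical
mature-length band; the full legal range is 18-25). Two construction
guarantees make downstream truth unambiguous:

* equal-length sequences differ at >= 3 positions, so a read carrying at
  most one substitution can never sit within the SNV tolerance of two
  equal-length references;
* no sequence contains the adapter's 8-nt seed, so clipping can never
  truncate a genuine insert.

The 20-nt lower bound additionally ensures that an in-tolerance 2-nt 3'
trim can never push a read below the 18-nt length filter.

`simulate_abundances()` draws per-miRNA weights from a log-normal law,
default sigma 3 (a power law is available behind `law = "powerlaw"`). The
log-normal was chosen because tissue miRNA profiles are extremely skewed -
a handful of miRNAs carries most of the mass - while a long tail of rare
species keeps detection saturating slowly with depth. With the default
shape the top 10 of 300 miRNAs carry the majority of the mass and at least
20% of miRNAs fall below 1/(10n).

## Composition

`composition_profile()` fixes the fraction of *all* sequenced reads per
category: mature miRNA, structured ncRNA, repeat, unclassified, adapter
dimer. The tissue presets are parameterized by the category percentages
*among post-clipped reads* - the quantity a sequencing report states - and
scale the four analytic categories by `1 - dimer`:

* muscle-like: 68% mature / 7% ncRNA / 3% repeat / 22% unclassified of
  post-clipped reads, with a 5% dimer fraction;
* plasma-like: 21% / 25% / 0.21% / 53.79%, with a 15% dimer fraction.

The dimer fractions are engineering choices (no measured value exists);
plasma gets the larger one because low-RNA preps ligate adapter to adapter
far more often.

**Where isomiRs live.** Mature miRNAs carry pervasive 3' heterogeneity.
Reads whose 3' end is modified within the quantifier's tolerance
(trim/extension of 1-2 nt; `isomir_rate`, default 0.2) still count as
mature and are generated inside the miRNA category. Reads modified *beyond*
the tolerance (3' extension of 3-5 nt, or a 3-nt trim; `isomir_other_rate`,
default 5% of post-clipped reads) end up in the quantifier's "others"
ledger and are *not* counted as mapped; accordingly the generator carves
them out of the unclassified budget, keeping the mature-category fraction
equal to the mature-mapped percentage a pipeline reports. The 5% default
sits inside the 1-12% band typical for muscle tissue.

## Reads, errors and determinism

Every read is insert + adapter + random padding, truncated to
`read_length = 50` cycles; adapter-dimer reads start with the adapter at
position 0. miRNA-category reads carry one substitution with probability
`snv_rate` (default 0.1, i.e. ~0.5% per base over a 22-nt insert). Decoy
categories draw *error-free* from fixed pools generated once per reference
with >= 3 mismatches over the first 16 nt against every mature sequence:
applying substitutions to decoys could silently move one inside the SNV
tolerance and corrupt category truth, which would make ledger-based
validation meaningless. For the same reason ncRNA/repeat pool sequences are
28-40 nt - longer than any mature-plus-window read, so they are never even
length-compatible with a mature call.

Qualities are constant Q35 (comfortably above the Q28 QC gate), with an
optional per-cycle degradation switch for QC testing.

One global integer seed drives everything. Multi-library operations fan out
through `derive_seed(seed, k)`, a fixed integer hash, so library *k* of an
experiment is byte-identical whether simulated alone or within the full
design. An edit that would create an adapter-seed substring inside an
insert is redrawn (extensions) or dropped (substitutions): such reads would
otherwise clip early and desynchronize the ledger.

## What the generator does *not* emulate

Indels and multi-error reads; non-templated additions other than random 3'
bases; 5' isomiRs; precursor/hairpin structure; instrument artifacts
(phasing, cluster density); quality-dependent error rates; true biological
sequence families (decoys are random, so cross-mapping between paralogues
is absent). Tests passing on this generator therefore certify the
*bookkeeping and statistics* of the pipeline, not its robustness to the
full messiness of real libraries.

# Preprocessing

`clip_adapter()` clips at the leftmost exact occurrence of the adapter's
first `min_overlap = 8` bases. Exact seed matching was chosen over
mismatch-tolerant clipping because common clipper implementations differ in
version-dependent ways; an optional 1-mismatch mode exists behind
`max_mismatch = 1`, and `N` never matches the seed. An adapter at position
1 classifies the read as adapter-only (discarded); a read without the seed
- including a terminal partial overlap shorter than 8 nt - is retained
unclipped but flagged, a conservative choice that leaves the quantifier to
deal with it. `filter_length()` enforces the 18-nt minimum inclusively;
`qc_summary()` passes a library iff every cycle's mean quality is >= Q28
(inclusive). `collapse_reads()` canonically orders unique sequences by
descending multiplicity, then lexicographically, and conserves the total.

# Quantification

`classify_sequences()` assigns each unique post-clipped sequence:

* **mature**: a 5'-anchored comparison against some reference shows at most
  `max_snv = 1` substitution over the overlap *and* a 3' length difference
  within +/- `three_prime_window = 2` nt. A full local alignment is not
  used: with a global 1-substitution budget and an indel-free generator,
  5'-anchored Hamming comparison is equivalent and exactly reproducible.
  The 2-nt window is configurable because published tools display the
  mature/others boundary without stating a numeric tolerance.
* **others_isomir**: the 5' anchor holds (<= 1 substitution over the first
  16 nt) but the 3' window or the overlap budget fails - the isomiR ledger,
  reported separately and never counted as mapped.
* **ncrna / repeat**: exact full-sequence membership in the decoy pools
  (the generator introduces no errors in those categories, so exact lookup
  is truth-complete).
* **unclassified** otherwise.

Candidate search is exact by pigeonhole: one substitution over the first
16 nt leaves the first or second 8-mer intact, so hashing both 8-mers finds
every admissible reference.

Ambiguous mature reads (possible only across different reference lengths,
given the >= 3 separation within a length) go through
`resolve_multimappers()`: `uniform` (default, deterministic 1/k),
`em` (iterative reallocation proportional to current abundances - the
expectation-maximization idea used for multi-mapped small RNA reads -
converging when no allocated count moves by more than 1e-8, cap 500
iterations), or `discard`. A shared-read component with no uniquely mapping
read has no identifiable allocation; it falls back to a uniform split and
says so. Ties in the best-candidate choice break by (mismatches, |3'
offset|, id) - deterministic.

RPM is `count / library_size * 1e6` with the mapped total as denominator.
The composition report normalizes over post-clipped reads; its four-way
fractions (mature, ncrna, repeat, unclassified) sum to 1, with others
folded into unclassified and also reported on its own - matching the
accounting in which "others" reads are not mapped.

# Saturation and correlation

`subsample_reads()` samples *reads* (not miRNAs) without replacement -
multivariate hypergeometric on the multiplicities - because read-level
sampling preserves the sequencer's distribution. `detection_curve()` uses
*nested* (cumulative) subsamples by default: incremental depth growth reads
naturally as cumulative, and nesting makes "newly detected at this
increment" well-defined and non-negative; independent draws are available
behind `nested = FALSE`. Detected counts use thresholds {1, 3, 5, 10, 50}.

`correlation_curve()` computes the Spearman correlation (average ranks for
ties; a constant vector raises an error rather than yielding NaN) between
each nested subsample's per-miRNA profile and the full-depth profile, over
the miRNAs detected at full depth with zeros imputed for the subsample.
That support-set choice is one of three defensible options
(full-depth support / union / intersection); full-depth support keeps the
vector length fixed across depths and makes rho exactly 1 at full depth,
where the subsample *is* the full profile. Rank correlation on raw counts
equals rank correlation on RPM at fixed depth, so no normalization is
applied.

# Differential expression

The two-group machinery mirrors standard count-based small RNA analysis,
implemented from first principles and calibrated by simulation:

* **TMM factors** (`tmm_factors()`): weighted trimmed mean of M-values
  against a reference sample (the one whose upper quartile of scaled counts
  is closest to the mean upper quartile), doubly trimming M at 30% and A at
  5%, inverse-variance (delta-method) weights, factors rescaled to
  geometric mean 1.
* **Median-of-ratios size factors** (`median_ratio_size_factors()`): per
  sample, the median of gene-wise ratios to the geometric-mean reference
  profile over genes nonzero in every sample.
* **Common dispersion** (`estimate_common_dispersion()`): counts are scaled
  to a common size; each gene contributes the moment estimate
  `(s^2 - mu) / (mu^2 - s^2/n)` implied by `var = mu + phi mu^2`. The
  `- s^2/n` term removes the upward bias of `mu_hat^2` as an estimate of
  `mu^2`; without it the estimator is biased low and the exact test
  anti-conservative. The per-gene estimates are combined by an
  inverse-variance-weighted mean (weights `(mu/(1 + phi0 mu))^2` from a
  first-pass pooled fit, genes with scaled mean > 1): a plain ratio-of-sums
  pool weights genes by `mu^2` and is therefore dominated - and made very
  noisy - by the few most abundant miRNAs of a long-tailed profile. On the
  package's own null simulations the weighted form cuts the estimator's
  spread by roughly five-fold and restores the BH false-flag probability
  to its nominal level.
* **Exact test** (`nb_exact_test()`): per gene, counts are equalized to a
  common library size and rounded half-to-even to pseudo-counts, the test
  conditions on the gene's pseudo-count total, and the two-sided p-value
  sums the conditional probabilities of all outcomes no more likely than
  the observed one (conventions differ; this "minimum-likelihood" form is
  the one implemented). The conditional law of one group's sum given the
  total is free of the mean: binomial at `phi = 0`, a
  Dirichlet-multinomial-type law at `phi > 0`, computed by enumeration over
  the total - cost linear in the gene's total count, which is why the
  simulation studies run at ~30,000 reads per library. The *lower median*
  of the effective sizes is the common scale: being an order statistic, it
  does not move when a single (non-central) library is rescaled, so
  multiplying one library's counts by a constant leaves every p-value
  intact exactly under median-of-ratios normalization. (TMM can only honor
  that invariance approximately: its precision weights depend on absolute
  library size by definition.)
* **FDR**: Benjamini-Hochberg step-up at alpha 0.05; `bh_adjust()`
  validates and delegates to the standard step-up implementation.
* **log2 fold change**: group-2 vs group-1 normalized means with a 0.5
  pseudo-count on both means - used only for reporting, never for testing.
* **`group_t_test()`**: Welch (default) or pooled two-sample t for
  validation-style comparisons of read counts or delta-Cp values; two
  constant equal groups give p = 1 by convention (with a message).

Counts are rounded half-to-even to integers only at the entry to the exact
test (`round_counts()`, which reports how many cells changed); fractional
counts upstream (uniform/EM multimapper splits) are left exact.

# Study conditions and problem sizes

The packaged analyses and tests use: 300 reference miRNAs (600 for the
depth curves, where tail size matters), two groups of 9 replicates,
common dispersion 0.1, composition presets as above, 500,000-read libraries
for composition recovery, a 6.5M-read pool stepped by 1M from 500,000 for
saturation, a 1M-read pool stepped by 100,000 for correlation, and
~30,000 mapped reads per library for the differential-expression
simulations (the enumeration cost of the exact test scales with total
counts, and power at |log2FC| >= 2 on well-expressed miRNAs is already
saturated there). Differential-expression simulations filter to miRNAs
with mean count >= 5 before testing, the standard low-count filter for
count-based DE. The majority-recovery threshold for injected signal is an
engineering target, not a literature value.

# Known limitations

* The quantifier has no indel handling and trusts the 5' end; real
  small RNA data contains 5' isomiRs and indel errors.
* Decoy classification is exact-match by design and would undercount
  degraded real ncRNA fragments.
* The exact test enumerates the conditional law; genes with totals in the
  tens of millions would be slow (the intended problem sizes are far
  below that).
* TMM's single-library-rescaling invariance is approximate (precision
  weights), exact only for median-of-ratios.
* The common-dispersion model ignores gene-wise dispersion variation;
  tagwise/trended shrinkage is deliberately out of scope.
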