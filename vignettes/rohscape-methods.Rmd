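---
title: "Autozygosity from runs of homozygosity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Autozygosity from runs of homozygosity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rohscape)
```

## The problem

When the parents of an individual share recent ancestry, the offspring
inherits stretches of chromosome that are identical by descent (IBD) on both
copies. These *runs of homozygosity* (ROH) are the genomic signature of
inbreeding: their number (NROH), cumulative length (SROH) and length spectrum
record how the autozygosity arose — few long runs point to recent
consanguineous unions, many short runs to old, population-level processes
such as drift in small populations. rohscape implements the complete analysis
chain used in human population studies of western Mediterranean and similar
cohorts: PLINK-format input and quality control, sliding-window ROH
detection, length-class summaries and inbreeding coefficients, a classifier
for the origin of autozygosity, and detection of *ROH islands* — regions
where an excess of individuals in a population carry ROH.

## ROH detection

Detection follows the observational sliding-window scheme of PLINK 1.9 with
the standard parameter set for ~2.4M-SNP arrays, exposed through
`roh_params()`:

| parameter | default | meaning |
|---|---|---|
| `window_snps` | 30 | SNPs per scanning window |
| `window_max_het` | 1 | heterozygous calls tolerated per homozygous window |
| `window_max_missing` | 5 | missing calls tolerated per homozygous window |
| `window_hit_threshold` | 0.05 | fraction of covering windows that must be homozygous for a SNP to enter a run |
| `min_snps_segment` | 30 | minimum SNPs per emitted segment |
| `min_length_kb` | 300 | minimum segment length |
| `max_kb_per_snp` | 30 | maximum inverse SNP density inside a segment |
| `max_gap_kb` | 1000 | maximum gap between adjacent SNPs inside a segment |

Semantics follow the PLINK 1.9 manual: the 300-kb value is the *minimum
segment length*, the 30 kb/SNP value the maximum inverse density, the 1000-kb
value the maximum within-segment gap. Only full windows are formed, so SNPs
near chromosome ends are covered by fewer windows and the hit fraction uses
the actual covering-window count. Heterozygotes inside an emitted segment are
not re-filtered at segment level (window rules only), and windows are defined
by SNP count alone by default (`window_max_kb` is available but off, matching
the common practice of leaving `--homozyg-window-kb` unset). Segment
coordinates are the positions of the first and last SNP, 1-based inclusive;
length is `end − start + 1`; BED exports convert to 0-based half-open.

The implementation is validated against an independent brute-force oracle
(direct enumeration of windows, per-SNP hit fractions and runs) on hundreds
of random instances; equality is exact, not approximate.

## Length classes and inbreeding coefficients

Segments are partitioned into six classes: ROH1 [0.3, 0.5), ROH2 [0.5, 1),
ROH3 [1, 2), ROH4 [2, 4), ROH5 [4, 8], ROH6 (8, ∞) Mb. Bounds are half-open
upward except ROH6, which is strictly "> 8 Mb" (so 8 Mb exactly falls in
ROH5) — the convention under which the reference summary table used in the
tests is internally additive.

Two coefficients are computed per individual:

$$F_{ROH} = \frac{\sum_i \mathrm{len}(ROH_i \ge 1.5\,\mathrm{Mb})}{3\,\mathrm{Gb}}$$

The threshold is applied inclusively (≥ 1.5 Mb); the denominator defaults to
the conventional 3-Gb human autosome length and is configurable — synthetic
benchmarks pass the simulated genome length instead. `compute_f_roh()` is
non-increasing in the threshold, and at threshold 0 recovers total SROH.

$$F_{IS} = \frac{O(HOM) - E(HOM)}{N - E(HOM)}$$

with `O(HOM)` the observed homozygote count of the individual, `N` its
non-missing genotype count and `E(HOM)` the Hardy–Weinberg expectation summed
over variants, using the allele-count small-sample correction
$1 - 2p(1-p)\,n/(n-1)$ (the `--het` convention; a textbook no-correction mode
exists). A fully homozygous genome gives exactly 1; negative values indicate
heterozygote excess.

Population summaries (`summarize_population()`) derive carrier counts and
percentages, per-individual means and mean segment lengths per class, with a
totals row; the arithmetic is exercised against a transcribed published
summary table for six western Mediterranean population samples
(`wm_reference_summary()`). Three cells of that table as printed are
internally inconsistent with the table's own totals (one raw class SROH
value, its percentage, and one per-individual mean); since every raw cell
appears in at least three printed derived values, the corrupted cells are
uniquely reconstructible and the shipped transcription stores the repaired,
additive values.

The Spearman correlation structure of {NROH, SROH} × classes and F_ROH uses
average ranks for ties and orders variables by average-linkage clustering on
1 − ρ (the common heatmap convention; no method is canonical here, so both
choices are recorded rather than hidden). The weight of each class on F_ROH
is estimated by a linear mixed model with a population random intercept
(REML, via nlme), response and predictors z-scored so coefficients are
standardized; singular fits fall back to a fixed-effects model with a
warning, and structurally empty classes return NA coefficients rather than
being silently dropped.

## Origin of autozygosity

Two complementary views:

1. **SROH vs NROH (≥ 1.5 Mb).** `sroh_nroh_reference()` fits an OLS line in a
   reference cohort; individuals with a large positive residual carry more
   long-ROH sequence than their segment count predicts — recent
   consanguinity. Drift moves points along the line.
2. **F_ROH vs F_IS plane.** `classify_origin()` reads the position relative
   to the diagonal F_IS = F_ROH and the horizontal F_IS = 0. The published
   rules are qualitative ("close to the diagonal"), so the classifier makes
   them explicit: clearly negative F_IS (`< −eps`) → isolation/small Ne;
   F_IS within ±eps of zero with appreciable F_ROH → panmictic drift;
   F_IS > eps with the point closer to the diagonal than to the zero line
   (|F_IS − F_ROH| ≤ |F_IS|) → systematic inbreeding; otherwise
   indeterminate. The nearest-line reading was chosen over a fixed band
   around the diagonal because a fixed band of width eps = 0.005 would
   reject textbook systematic-inbreeding cases (e.g. mean F_ROH 0.0438 with
   mean F_IS 0.0343, a canonical strongly consanguineous profile whose
   coefficients differ by 0.0095 simply because F_ROH also captures drift);
   the nearest-line rule is parameter-sparse and scale-free — multiplying
   F_ROH, F_IS and eps by a common constant never changes a label. `eps`
   defaults to 0.005 and distances are reported so users can re-threshold.

## ROH islands

Each chromosome is tiled with non-overlapping 100-kb windows (tiling rather
than a sliding stride: counts are defined "in every 100-kb genomic window",
and tiling keeps the testing family well-defined; a stride would multiply
correlated tests). Per window, the count of distinct individuals with ≥ 1 bp
of ROH overlap is compared with a one-sided exact binomial tail
P(X ≥ count | n, p₀) at a Bonferroni-corrected level. Two conventions are
supported for the family size: the actual number of windows tested (default)
and a fixed 2,500-window family reproducing the conventional 2 × 10⁻⁵
per-window threshold. The null proportion p₀ is not specified by the
published procedure; the default is the realized genome-wide mean per-window
carrier proportion, `sum(counts) / (n × #windows)` — the only self-contained
choice that makes "more individuals than expected" well defined — with an
override for externally calibrated values.

Adjacent significant windows merge into islands (gap 0). Island sharing is
the percentage of individuals with any ROH overlap of the island. Matching
islands across populations uses *reciprocal* 75% overlap — "share at least
75% of their length" is ambiguous about whose length; the reciprocal reading
is symmetric and stricter. Filters keep islands with sharing ≥ 90% or length
≥ 1.5 Mb (both inclusive). Metapopulation analysis re-runs the pipeline on
pooled samples; a group of one population reduces exactly to the
per-population run. Gene overlap against a user-supplied BED/GFF3 annotation
(read via rtracklayer) reports genes with ≥ 1 bp overlap; zero-width
abutment at the half-open island end does not count.

## The synthetic-data generator

All validation runs on synthetic genotypes with known ground truth, because
the real cohorts this analysis chain targets are controlled-access. The
generator emulates:

- **Founders / outbred panmixia** — evenly spaced biallelic SNPs with
  frequencies uniform on [0.05, 0.5], genotypes in Hardy–Weinberg
  proportions. Sites are independent (no linkage disequilibrium).
- **Consanguineous pedigrees** (`simulate_cohort()`, `gene_drop()`) —
  founder haplotypes are transmitted down selfing, first-cousin or
  second-cousin pedigrees with recombination: crossover counts per
  chromosome are Poisson with mean equal to the map length in Morgans
  (1 cM/Mb default), positions uniform, no interference. Haplotypes carry
  founder-segment identity, so ground-truth autozygous tracts are defined at
  founder-haplotype resolution — regions where both copies descend from the
  same founder haplotype. This is what "identical by descent" requires;
  short chance-IBS runs are deliberately *not* truth.
- **Drift** (`simulate_drift()`) — a discrete-generation Wright–Fisher
  diploid population of constant size with random mating and recombination.
- **Planted islands** (`plant_island()`) — a carrier fraction of individuals
  made homozygous for one fixed haplotype over a region.
- Optional missingness and genotype-error injectors exercise the QC filters.

The desk-scale default (`sim_config()`) is 4 chromosomes × 50 Mb at 20-kb
spacing (10,000 variants): large enough to resolve ≥ 1.5 Mb ROH statistics,
small enough that the full test suite runs in about a minute. Two
consequences of this scale are worth stating because they bound what the
tests show about real data:

- At 20-kb spacing, segments shorter than ~580 kb cannot satisfy the 30-SNP
  minimum, so the ROH1 class is structurally empty in default-scale
  simulations; tests of the short classes use 10-kb spacing. Real arrays are
  ~10× denser, so this is a resolution artifact of the benchmark, not of the
  method.
- The 200-Mb genome is only ~2 Morgans, so the per-offspring realized
  autozygosity fraction has SD ≈ 0.085 for first cousins. The mean-recovery
  benchmark therefore uses 500 offspring: at least 289 are needed for the
  95% band of the cohort mean to fit within ±0.01 of the pedigree
  expectation 1/16 (the check requires a minimum of 200; more is legitimate
  and reduces seed sensitivity).

The generator also does not emulate LD structure, variable recombination
maps, genotyping error biases or array ascertainment; passing benchmarks
demonstrate correctness of the algorithms under the stated model, not
robustness to those real-data features.

Calibration of island detection uses a segment-level null
(`simulate_null_roh_table()`): ROH placed uniformly at random with Poisson
counts per individual. A genotype-level panmictic null is vacuous here — an
outbred genome with independent sites at these frequencies has ~11 expected
heterozygotes per 30-SNP window, so the caller emits essentially no ROH and
every window count is zero. The segment-level null produces the spatially
uniform carrier counts that the binomial model actually assumes, which is
exactly what a false-positive-rate check needs. Island *power* is still
checked end-to-end at the genotype level (plant, call, detect) with 10-kb
spacing, so a 500-kb planted region holds enough SNPs to be callable — at
20-kb spacing a 500-kb region holds only ~26 SNPs and no parameter-faithful
caller can emit it, an arithmetic constraint of the standard parameters
worth knowing when designing small simulation studies.

## Numerical and degenerate-input choices

- The exact Hardy–Weinberg test is the exact conditional test (no mid-p),
  computed from the conditional distribution of the heterozygote count given
  allele counts in log space; ties between support points are compared with
  a 1e-12 relative guard so floating-point noise cannot flip a tie.
  Monomorphic variants return p = 1. Tests verify agreement with an
  independent enumeration oracle built from the unconditional multinomial.
- QC order is fixed and recorded: sample missingness → variant missingness →
  exact HWE. The operation is idempotent, conserves counts, and errors if
  every sample would be removed.
- `pairwise_pihat()` is the method-of-moments IBS→IBD inversion with each
  IBD-state estimate clamped to [0, 1]; pairs ≥ 0.5 are flagged. Variants
  with zero non-missing calls are excluded with a warning.
- Zero-variance variables yield NA correlations (reported, not dropped);
  degenerate F_IS denominators (N = E_hom) return NA with a warning; a
  reference regression on zero-variance NROH is an error.
- All stochastic operations require a seed and are bit-reproducible given
  (configuration, seed).

## A worked example

```{r example}
cfg <- sim_config(n_chromosomes = 2, chromosome_length_bp = 3e7,
                  snp_spacing_bp = 2e4)
fc <- simulate_cohort(cfg, "first_cousin", 30, seed = 101)
tab <- call_roh(fc$dataset)
recs <- inbreeding_records(tab, dataset = fc$dataset, genome_bp = 6e7)
c(mean_f_roh = mean(recs$f_roh), mean_f_is = mean(recs$f_is))
classify_origin(mean(recs$f_roh), mean(recs$f_is))
```

The cohort mean of both coefficients estimates the pedigree expectation
1/16 = 0.0625 (up to the sampling noise discussed above), and the origin
classifier places the cohort on the diagonal of the F_ROH/F_IS plane —
systematic inbreeding.

## Limitations

- The caller is the observational window scan, not a likelihood/HMM method;
  it inherits the known sensitivity of window methods to marker density and
  calling parameters, which is why the parameters are explicit, recorded in
  every `roh_table`, and fixed to the conventional array values by default.
- Autosomes only; no imputation, phasing or build liftover.
- The binomial island test treats windows as independent; long ROH spanning
  several windows induce positive correlation between neighbours. Bonferroni
  control over marginal tests remains valid (and conservative), but island
  *counts* should not be read as independent discoveries.
- `islands_step1`-style per-population runs with very different sample sizes
  have very different power; the metapopulation pooling exists precisely to
  mitigate that, and comparisons across populations should use the matching
  rules, not raw counts.
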