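---
title: "Methods: region-based ctDNA quantification from cfDNA methylation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: region-based ctDNA quantification from cfDNA methylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cashcandi)
```

## The model

Circulating tumor DNA is quantified by counting sequencing reads that
look unambiguously tumor-derived. Two properties make a read
unambiguous: it lies entirely within a region that is hypermethylated in
tumor tissue but unmethylated in normal tissue *and* in the cfDNA of
healthy donors, and the read itself is densely methylated (read
methylation density RMD > 0.6). Because the background at such a region
is doubly controlled — against adjacent normal tissue and against
healthy plasma — the false-candidate rate from blood-derived cfDNA is
very low, and a simple CPM-normalised average of per-region candidate
counts (ctCandi) behaves like a tumor-fraction estimate.

### Region discovery

Per CpG site (strand-collapsed to the plus-strand C), β = methylated /
total reads, with a minimum-coverage floor below which the value is
treated as missing. Discovery proceeds:

1. drop CpGs missing in more than half of the samples of any discovery
   group (strictly more than: exactly half keeps the site);
2. per CpG, two-sided Wilcoxon rank-sum test of tumor vs normal β, BH
   adjustment over all CpGs that survive the missingness filter;
3. keep CpGs with Δβ > 0.3 (strict), healthy-plasma mean β < 0.05
   (strict), q < 0.05;
4. merge surviving CpGs whose 75 bp flanks touch or overlap
   (equivalently: position gap ≤ 150 bp) into fragments;
5. drop fragments with fewer than ten CpGs;
6. a region spans the first to the last member CpG, 1-based inclusive.

Hypomethylated discovery mirrors the rule: Δβ = β_normal − β_tumor,
plasma mean β > 0.95, candidate reads have RMD < 0.3.

### Scoring

For one plasma sample with `N` total mapped (deduplicated) reads and
regions `r = 1..R` with candidate counts `c_r`:

ctCandi = (1/R) Σ_r c_r · 10⁶ / N.

Zero-count regions stay in the mean. Every mate of a read pair is an
independent read. Reads longer than a region can never be contained in
it; regions near the 52 bp minimum therefore contribute structurally
zero counts, which the scorer flags in its log rather than silently
hiding.

## Decisions made where the design was open

* **Per-CpG test and FDR.** The discovery FDR is not tied to a named
  test in the source description; we use the two-sided Wilcoxon
  rank-sum test per CpG with Benjamini–Hochberg adjustment, the
  rank-based test used everywhere else in this workflow. BH runs once,
  over all missingness-surviving CpGs and *before* the β-threshold
  filters, so q-values do not change when the plasma filter is
  tightened.
* **Plasma filter.** "β below 0.05 in healthy plasma" is read as a
  condition on the group mean; `plasma_mode = "all"` switches to
  requiring every healthy-plasma sample below the threshold.
* **Merge tie-break.** A CpG gap of exactly 150 bp (= 2 × 75) merges:
  touching closed intervals chain.
* **Region ends.** Regions end at the C position of the last member
  CpG, not the G of the dinucleotide; the printed example lengths
  (1966 bp, 1469 bp) are consistent with this convention.
* **Coverage floor.** β calls need ≥ 5 reads by default. The source
  workflow is silent; low-coverage β values are pure noise against a
  0.3 Δβ threshold, and 5 reads at 30× coverage discards almost
  nothing.
* **Mixing by replacement.** In-silico dilution replaces plasma reads
  with tumor reads instead of adding them, so the total read count —
  the CPM denominator — is constant across the series and ctCandi
  differences reflect composition only.
* **Paired region contributions.** The pre/post "pairwise rank" test on
  matched patients is implemented as the paired Wilcoxon signed-rank
  test (the data are matched within patient), with exact enumeration of
  the 2^n sign assignments for ≤ 12 non-zero differences — valid under
  tied magnitudes, where the textbook exact distribution is not — and a
  tie- and continuity-corrected normal approximation otherwise.
* **Unpenalized logistic fit.** With per-region features the training
  folds are typically completely separable and the unpenalized MLE does
  not exist. Newton/IRLS then drifts to an essentially arbitrary
  separating direction which ranks held-out samples poorly. We minimise
  the (unpenalized) negative log-likelihood with L-BFGS from a zero
  start and a 100-iteration cap — the estimator family of the standard
  scikit-learn implementation this workflow originally used — whose
  early-stopped direction is gradient-dominated and generalises. The
  fit logs when the cap binds; AUC is invariant to monotone rescaling
  of the scores.
* **Youden operating point.** Sensitivity/specificity are reported at
  the threshold maximising J = sensitivity + specificity − 1 on each
  fold's out-of-fold ROC, ties broken toward higher specificity.

## The synthetic world

The generator (`synth_config()` defaults) states the simulated world:

| parameter | default | why |
|---|---|---|
| genome | 2 chromosomes × 1 Mb | large enough for 50 well-separated regions, small enough for seconds-scale runs |
| planted regions | 50, pairwise ≥ 2 kb apart | the discovery recovery target |
| CpGs per region / span | 18 CpGs / ~420 bp | matches the reported ~400 bp mean marker-region length; ~24 bp spacing, far below the 150 bp merge gap, so each region forms one fragment |
| background CpG rate | 0.001 per bp | see the power analysis below |
| planted β means | tumor 0.90, normal/plasma 0.02 (Beta, concentration 50) | Δβ ≈ 0.88 > 0.3 and plasma < 0.05 in expectation, so planted regions satisfy the discovery thresholds by construction |
| background β | mean 0.05, concentration 20, all groups | null sites; the probability of a 5v5 empirical Δβ > 0.3 is ≪ 1 per genome |
| conversion error ε | 0.005 | typical post-conversion error; applied symmetrically, so the effective methylation probability is m(1−2ε)+ε |
| reads | 150 bp single-end, 30× | read length and depth of the emulated assay; 30× of 2 Mb = 400,000 reads |
| case tumor fraction | uniform on [0.5%, 5%] | the upper half of the dilution grid |
| cohort | 49 cases / 60 controls | the evaluated cohort shape |

**Why the background CpG rate is 0.001/bp.** The discovery design is
fixed at 5 tumor vs 5 normal samples. A 5v5 Wilcoxon rank-sum test has
an exact two-sided p-value floor of 2/C(10,5) ≈ 0.0079 (up to ~0.012
with tie corrections when several normal samples have β exactly 0).
Benjamini–Hochberg over m tested CpGs can therefore only reach
q < 0.05 if the truly differential sites make up at least roughly
p·m/(0.05·m) ≈ 16–24% of all sites. This is a property of the test and
the design, not of the data: at human genome-wide CpG density the same
5v5 design would (correctly) report *no* site at FDR < 0.05, no matter
how clean the signal. The toy genome is therefore a marker-panel-like
miniature: 900 planted CpGs against ≈ 2,000 background CpGs (≈ 31%
planted), fixed a priori from this power analysis. Tests of the null
behaviour (no planted signal → zero regions) are unaffected by this
choice.

**What the generator does not emulate.** Fragment-size distributions
and end motifs of real cfDNA, sequence-dependent coverage bias,
co-methylation structure beyond the per-sample site level (within a
read, calls are independent Bernoulli draws), haplotype effects, and
hg38 CpG geography. A green test therefore establishes that the
algorithms implement the stated model and that the pipeline has the
expected dose-response and discrimination *under that model* — not
clinical performance on real plasma.

**Scaled-down cohort emission.** `make_cohort()` materialises only
reads whose span overlaps a marker-region window (region padded by one
read length) and records the notional genome-wide total
(coverage × genome / read length) as the CPM denominator. Reads outside
the windows can never be candidates, and both the plasma and tumor read
profiles place reads uniformly, so per-region counts and CPM are
distributionally identical to full emission at ~1% of the cost. The
dilution series uses full genome-wide read sets.

## Numerical choices

* Exact rank-sum enumeration (via the closed-form null distribution)
  when n₁+n₂ ≤ 12 and no ties; otherwise normal approximation with tie
  and continuity corrections.
* Spearman ρ uses average ranks; p by exact permutation for n ≤ 8,
  t-approximation otherwise; |ρ| = 1 reports p = 0.
* `round(fraction × N)` fixes mixture composition (R's round-half-even
  applies at exact .5).
* Derived seeds are drawn as `sample.int(2^31 − 2, n)` inside a single
  seeded block, so every internal seed is a valid 32-bit integer seed
  regardless of the user's master seed.
* Degenerate inputs: empty region lists, zero-CpG reads (RMD
  undefined → ineligible), all-equal scores (AUC 0.5 by the tie
  convention; Youden J = 0 at the all-negative point), all-zero paired
  differences (p = 1) are all defined rather than errors, except where
  the contract demands failure (empty groups, overlapping regions,
  single-class folds).

## Known limitations

* Paired-end mates are never reunited into fragments; a fragment
  covered by both mates is counted twice (consistent with counting
  "reads").
* SAM/BAM input requires Bismark-style XM tags and takes reference
  coordinates from the alignment; reads without XM are an error, not a
  fallback.
* The CPM denominator is the genome-wide mapped read count; a
  region-restricted denominator would change the scale (not the
  ranking) of ctCandi.
* With very small discovery cohorts the FDR gate dominates discovery
  power (see the power analysis above); real studies should use the
  cohort sizes the assay was designed for.
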