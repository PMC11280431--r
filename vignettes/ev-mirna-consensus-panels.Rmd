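---
title: "Consensus differential expression and cross-biofluid panel selection for EV miRNA"
author: "evmirpanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus differential expression and cross-biofluid panel selection for EV miRNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evmirpanel)
```

## The problem

Extracellular vesicles (EVs) in accessible body fluids carry miRNA cargo
that reflects the tissue of origin, which makes EV miRNA profiles a
candidate liquid-biopsy readout for ovarian cancer. The analytical
difficulty is that count-based differential-expression (DE) tests on small
RNA-seq data disagree at the margins: each popular framework makes different
dispersion and normalization choices, and a single-engine call list is
inflated by method-specific artifacts. This package implements a deliberately
conservative procedure for deriving a tiered miRNA marker panel from
miRNA-by-sample count matrices collected in four groups:

* **UA-N** — uterine aspirates of non-cancer controls (the common reference),
* **UA-OC** — uterine aspirates of ovarian-cancer patients,
* **AF** — ascitic fluid of ovarian-cancer patients,
* **AC** — conditioned medium of ascites-derived tumour cells in primary
  culture.

The procedure has three stages: (1) three statistically distinct DE engines
are run on each two-group contrast; (2) a miRNA is accepted only on
*unanimous* agreement under shared thresholds, at two FDR tiers; (3) the
accepted sets are intersected across biofluids in a direction-aware way, on
the reasoning that a miRNA genuinely tied to the tumour should shift in the
same direction in every fluid that contacts it, and increasingly so as the
fluid gets closer to the tumour.

## The consensus model

Each engine tests the same two-group contrast on the same post-filter miRNA
universe and reports a log2 fold change (case over control), an average
abundance (logCPM), a test statistic, a p-value, and a Benjamini–Hochberg
adjusted FDR:

* `engine_nb_lrt` — TMM normalization, negative-binomial GLM with
  empirical-Bayes dispersion shrinkage toward an abundance-dependent trend,
  likelihood-ratio test (the classic edgeR pipeline);
* `engine_voom_lm` — log-CPM with a lowess mean–variance trend supplying
  per-observation precision weights, weighted linear model, moderated
  t-statistic (limma-voom);
* `engine_nb_wald` — median-of-ratios size factors, parametric dispersion
  trend with log-normal shrinkage, Wald test on the log2FC coefficient
  (DESeq2).

A miRNA is called **up** or **down** at the base tier only when *every*
engine reports FDR < 0.01, |log2FC| > 1 (fold change > 2) and logCPM > 2,
with all three signs agreeing; sign disagreement forces a non-significant
call even if each engine is individually significant. The strict tier
additionally requires FDR < 0.001 from every engine and is by construction
nested in the base tier. The fold-change criterion is evaluated per engine on
that engine's own estimate, because the point of the consensus is that every
framework independently clears every bar. The consensus table reports the
negative-binomial LRT engine's log2FC as the representative estimate.

These engines are the established implementations, wrapped behind a uniform
surface; the package's own contribution is the consensus rule, the set
algebra, and the simulator. The wrappers are validated in the test suite
against independent brute-force oracles (the TMM trim-and-weight formula,
the median-of-ratios definition, the closed-form two-group Poisson deviance
in the zero-dispersion limit, a hand-rolled BH step-up) and by calibration
and recovery simulations.

### The abundance filter

The expression criterion logCPM > 2 is applied *before* testing, and the BH
denominator is the post-filter count. Filtering first is the standard
practice for count pipelines (low-abundance rows carry no power and dilute
the FDR correction), and computing the filter once — from TMM-normalized
average logCPM on the contrast submatrix — guarantees that the three engines
test identical universes, which the consensus requires. The alternative
convention (test everything, adjust over everything, drop low-abundance rows
afterwards) is available via `filter_before = FALSE`; it changes the BH
denominator and is deliberately not the default.

## Cross-biofluid set algebra

From the reference contrast (UA-OC vs UA-N) the base-tier calls form the
reference set ("set 1") and the strict-tier calls its subset ("set 2"). For
each tumour-proximal fluid the reference set is partitioned by
`codirectional_partition()` into six exhaustive, disjoint subsets:

| subset | meaning (relative to the reference direction) |
|---|---|
| a / c | significantly co-directional vs *both* the control and UA-OC (up / down) |
| b / d | significantly co-directional vs the control only (up / down) |
| e | non-significant vs the control |
| f | significantly changed in the *opposite* direction |

Subsets are labelled 3a–3d for the ascitic-fluid partition and 4a–4d for the
ascites-cell partition (the published figures reuse "3a–3d" for both; the
4-prefix disambiguates). MiRNAs co-directional (a–d) in both partitions form
the all-fluid co-directional set ("set 5").

The final panel consists of strict-tier miRNAs co-directional in at least
one of the two partitions, with membership in subset f of *either* partition
an outright exclusion — an opposite-direction change anywhere undermines the
causal reading, so it vetoes the marker even if the other fluid agrees.
Members co-directional in both fluids form the `three_fluid` tier, members
co-directional in exactly one the `two_set` tier. This formalization of
"consistent in at least two sets" reproduces the published tier counts
(17 three-fluid + 12 two-set = 29 of 35) when applied, via
`classify_table3()`, to the packaged transcription of the published
per-miRNA status table — a pure set-logic path that bypasses the engines and
is what `scripts/acceptance.R` recomputes.

A reference miRNA can be missing from a comparison universe when the
abundance filter removes it in that contrast; it is assigned to subset e
with a warning rather than an error, since "not testable" and "not
significant" have the same consequence for the panel.

## The synthetic cohort generator

No raw study data ships with the package, so `simulate_counts()` generates
cohorts with the study's structure. Counts are negative-binomial with mean
\(\mu_{ij} = L_j \, p_i \, 2^{fc_i(g_j)}\) and variance
\(\mu + \phi(\mu)\mu^2\):

* \(L_j\): per-sample library size, log-normal with mean `lib_size_mean`
  (default 1e6 miRNA-mapped reads — a typical small RNA-seq yield once
  non-miRNA classes are removed) and CV `lib_size_cv` (default 0.35,
  heavy-tailed depths being the norm);
* \(p_i\): baseline relative abundances, drawn once per simulation on a
  uniform log2 scale over `baseline_logmean_range` (default −15 to −4, an
  ~2,000-fold dynamic range that yields the handful of dominant miRNAs that
  make composition-robust normalization earn its keep) and shared across
  groups;
* \(\phi(\mu) = \) `dispersion_intercept` + `dispersion_slope`\(/\mu\)
  (defaults 0.1 and 3): a biological CV of ~0.32 for abundant miRNAs with
  the usual inflation at low counts. The study reports no dispersion or
  depth estimates, so these defaults are chosen for plausibility, not
  fidelity;
* group sizes default to the study's 25/56/58/23 (UA-N/UA-OC/AF/AC);
  1,500 miRNAs by default — consistent with what the published adjusted
  p-values imply about the size of the tested universe (the top row's
  FDR/p ratio puts it near 1.3–1.4k);
* a fraction `frac_de` (default 0.1) of miRNAs receives planted
  co-directional effects with |log2FC| drawn from `effect_log2fc_range`
  (default 1–3, i.e. fold changes 2–8 bracketing the detectability
  threshold); a fraction `frac_monotone` of those (default 0.5) gets
  magnitudes sorted to increase along UA-N → UA-OC → AF → AC, emulating
  markers whose signal strengthens as the fluid approaches the tumour.

All randomness flows from one integer seed; identical configs give
bit-identical cohorts. The generator emulates count overdispersion, depth
variation, composition effects and planted co-directional structure. It does
**not** emulate batch effects, sample swaps, non-miRNA RNA classes,
grade-correlated expression, or any sequence-level structure — so passing
recovery tests demonstrate that the pipeline's logic and statistics behave
correctly under its own model assumptions, not that the published biological
findings would replicate on new cohorts.

## Numerical and design choices

* **log-CPM prior.** `log_cpm()` adds a prior of
  `prior_count × lib/1e6` per sample (default 0.5 per million reads), which
  makes the transform exactly invariant to a global rescaling of counts and
  depths and keeps `log2 ≈ −1` for a zero count in a 1e6 library. Reported
  `logCPM` abundance uses the likelihood-based average (prior 2), the
  convention of the published result tables.
* **Zero p-values** are floored at the smallest positive double before BH
  adjustment, so FDRs stay in (0, 1].
* **Ties in BH** are handled by the step-up cummin, identical to the
  brute-force definition (oracle-tested on 1,000 random vectors).
* **TMM reference sample** is the column whose upper-quartile count fraction
  is closest to the cohort mean; trims are 30% (M-values) and 5% (A-values)
  per tail.
* **Dispersion shrinkage prior** for the LRT engine defaults to 10 prior
  degrees of freedom (configurable).
* **MDS** uses the pairwise leading-fold-change distance (root-mean-square
  of the `top_n = 500` largest per-pair log-CPM differences) and classical
  Torgerson scaling, with a deterministic sign convention (the
  largest-magnitude coordinate on each axis is positive). The published
  ordination figures do not state their distance; this convention matches
  the framework whose MDS plots they show, and the package's group-separation
  checks are property-based (silhouette width), not coordinate-matching.
* **Grade subgroups.** `subgroup_contrast()` reuses the full three-engine
  consensus for metadata-defined contrasts (e.g. G2/G3 vs G1 within UA-OC).
  Whether the original grade comparison demanded three-package agreement is
  not stated; applying the same machinery uniformly is the conservative
  choice.
* **Fixture ambiguity.** The published status table lists one ID
  ("miR-6393p") matching no result-table row; the packaged transcription
  maps it to the presumed intended row (miR-539-3p), keeps the printed
  string, and flags it `ambiguous`. The row is non-significant in both
  comparison columns, so no panel count depends on the resolution, and tests
  assert only on unaffected rows. Published percentages are reported as
  exact fractions (e.g. 44/79), with no rounding convention encoded.

## What the tests compute

The suite validates each layer at sizes chosen to keep a full run within a
few minutes while retaining power: oracle checks on toy matrices; null
calibration at 2,000 miRNAs and the study's 25-vs-56 reference contrast
(each engine's type-I error at p < 0.05 inside the binomial 99% CI);
consensus false-discovery proportion below 0.05 averaged over 20 seeded
cohorts of 1,000 miRNAs; log2FC recovery bias below 0.1 for planted
|log2FC| = 2 effects; and recovery of monotone planted miRNAs into the
three-fluid tier with recall at least 0.8 over 20 seeded four-group cohorts
of 400 miRNAs at planted |log2FC| between 2 and 3. The analysis drivers
under `analysis/` run the same pipeline once at the full default scale
(1,500 miRNAs, 162 samples) and write every table under `results/`.

## Known limitations

* The engines are wrapped third-party implementations; their exact numeric
  output can drift across upstream releases, while the consensus logic, set
  algebra and simulator are version-stable package code.
* Only two-group contrasts are supported — no multi-factor designs,
  continuous covariates, quasi-likelihood tests, or outlier replacement.
* The consensus is unanimous by design and therefore conservative; it
  trades sensitivity for robustness, which is the procedure's point but
  should be remembered when comparing call counts with single-engine runs.
* Published cohort-level counts that depend on the raw sequencing data
  (e.g. the 79-member reference set) are reproduced only structurally on
  synthetic data; what is reproduced exactly is everything computable from
  the printed tables.
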