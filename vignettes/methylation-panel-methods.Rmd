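---
title: "Methods: cfDNA methylation marker discovery and qMSP panel evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cfDNA methylation marker discovery and qMSP panel evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdmpanel)
```

## The problem

Esophageal cancer is usually found late because early disease is
asymptomatic and endoscopy is too invasive for population screening. Tumor
DNA sheds into plasma as cell-free DNA (cfDNA), and tumor-specific
hypermethylation appears early in oncogenesis and is less heterogeneous
than mutations, so a small panel of methylated DNA markers (MDMs) assayed
by quantitative methylation-specific PCR (qMSP) in blood is a plausible
screening instrument. This package implements the full computational side
of such a program: tissue-based marker discovery, plasma signal
thresholding, qMSP call interpretation, and diagnostic-performance
evaluation, together with a synthetic cohort generator and count tables
reconstructed from a published clinical program, so the whole chain is
testable without access to any raw cohort.

## Marker discovery

Discovery operates on region-by-sample matrices of methylation levels
(beta values in [0,1]). Tissue screening applies three conjunctive
criteria per region:

* adjusted p < 1e-2 for the tumor vs adjacent-normal two-group test,
* delta_T2N (tumor mean minus adjacent-normal mean) > 0.1,
* mean WBC methylation < 0.1, a background filter: cfDNA is dominated by
  white-blood-cell DNA, so a usable plasma marker must be silent in
  leukocytes.

The two-group test defaults to the Wilcoxon rank-sum: beta values are
bounded and often skewed, rank tests are the robust default for such data,
and the same family of tests is used elsewhere in the pipeline. Welch's t
is available as a config option. Multiplicity adjustment defaults to
Benjamini–Hochberg across all testable regions — the community default
for DMR screens — with Bonferroni as the conservative alternative; which
adjustment the original program used is not stated, so both are exposed.
Missing values are excluded pairwise and never imputed; a region with
fewer than two usable values on either side is flagged untestable and
excluded from the adjustment denominator rather than given a fake p-value.

Plasma carries a strong background, so plasma signals are binarized by the
*one-hot transform*: the per-region detection threshold is the 95th
percentile of plasma levels in cancer-free controls, which targets 95%
specificity per region by construction. Quantiles use linear interpolation
between order statistics (R type 7), and the comparison is strict: a
control sitting exactly at the threshold is *not detected*. Detected
levels keep their value; everything else becomes zero.

Panel selection fits an L2-regularized (ridge) logistic model of
case/control status on the one-hot signals of screened regions and ranks
regions by absolute standardized coefficient, ties broken by smaller
adjusted p. Ridge rather than an unpenalized fit because one-hot signals
separate perfectly in small discovery sets, and the fit must stay finite;
the penalty is a fixed small lambda (0.01) rather than cross-validated so
that selection is deterministic. The top k regions are refit alone to give
the reported model.

Probe harmonization between the two array platforms pairs probes whose
design intervals overlap or lie within 150 bp of each other on the same
chromosome (the gap boundary is inclusive). Coordinates are 0-based
half-open (BED) everywhere inside the package; interval work is delegated
to GenomicRanges.

## qMSP interpretation

A sample is interpretable only if its ACTB reference gene amplified at
Ct ≤ 34.8 cycles and, when a plasma cfDNA concentration was recorded, that
concentration is ≥ 0.9 ng/mL. Both bounds are inclusive, matching the
stated acceptance rules of the assay. QC failures become `no_call` and are
excluded from all performance denominators (and tallied separately).

Per marker, a call is *positive* iff the marker amplified at or below its
cutoff — inclusive, mirroring the ACTB rule. No amplification means no
methylated template and is an explicit negative, never an imputed Ct. The
panel combines marker calls by the parallel (OR) rule: positive if any
valid marker call is positive. Parallel combination maximizes sensitivity,
which is the design goal of a screening assay; a logistic combination over
reference-adjusted Ct features is provided as the alternative mode, and on
simulated cohorts the two agree closely (the original program also found
them near-equivalent and chose parallel). A possible 2-of-3 voting reading
of "parallel" was considered and rejected: standard usage of parallel
testing in diagnostics is the OR rule.

The methylation risk score is 45 − ΔCt with ΔCt = marker Ct − ACTB Ct,
undetected markers imputed at the 45-cycle ceiling, and the panel score
the maximum over markers (tracking the strongest signal). Higher score =
more methylated cfDNA. The 45-cycle constant is the run length implied by
the score's published form; a marker-Ct-only variant (45 − Ct) sits behind
a config switch since the published description is ambiguous about the
reference adjustment.

The per-marker positivity cutoffs used in the original trial are not
published. `calibrate_cutoffs()` is the package's substitute: each
marker's cutoff is the largest Ct keeping marker-level specificity on
training controls at or above a target (default 95%); with clean controls
the cutoff is the ceiling itself, i.e. any amplification is positive.

## Evaluation

`panel_metrics()` computes sensitivity, specificity, PPV, NPV, accuracy
and Youden's J from 2×2 counts, each with a binomial CI; undefined
metrics (zero denominator) are NA, never 0. Cohen's κ carries a
Fleiss-style asymptotic-SE confidence interval — the published program
promises κ CIs but never prints one, so the standard large-sample form
was chosen. Three binomial CI constructions are provided (Wilson score,
Wald clamped to [0,1], Clopper–Pearson exact) because the published
intervals demonstrably mix methods across sections: the overall
sensitivity CI matches Wilson, per-stage CIs match Wald, and the subgroup
tables match Clopper–Pearson. Reports label the method used; Wilson is
the default.

The ROC is the empirical curve over unique thresholds with ties grouped,
and AUC is its trapezoidal integral, which equals the Mann–Whitney
concordance probability — the test suite checks this identity against an
exhaustive pairwise count and against an independent ROC implementation.
Paired pre/post comparisons use the Wilcoxon signed-rank test with zero
differences dropped; independent groups route to the rank-sum variant.

Printed-percentage comparisons round half away from zero to 2 decimals
(`round_half_up()`), the convention under which every reconstructed table
reproduces its printed percentage exactly.

## The synthetic generator

`generate_qmsp_cohort()` emulates a clinical cohort: group sizes default
to the validation-cohort composition (32/106/111/204/117 cancer cases at
stages 0–IV, 71 unknown, 298 benign, 292 healthy, 198 other cancers of
five types). Each marker is detected with a per-(group, marker)
probability; detected Cts are normal truncated at the 45-cycle ceiling
(mean 33, sd 3 cycles — a plausible low-template qMSP regime), ACTB is
normal (mean 30, sd 1.5) truncated at the QC gate, and a configurable
fraction of samples is pushed above the gate to exercise QC handling.
Detection probabilities are calibrated by inverting the OR rule,
p = 1 − (1 − s)^(1/3) with s the observed per-group panel rate, under
equal allocation across the three markers — the published data do not
constrain the per-marker split, and equal allocation is the maximum-
entropy choice. As detection probabilities go to 0 or 1 the panel rate
follows monotonically, which the tests verify.

`generate_discovery_data()` plants `n_dmr` hypermethylated regions among
`n_regions`: tumor mean `base_beta + delta_planted` (defaults 0.2 + 0.4),
adjacent `base_beta`, WBC `wbc_beta` (0.05), with Beta noise at
concentration 30. Plasma controls sit at the WBC background; case plasma
carries the signal at a planted region with probability
`plasma_signal_rate` (0.6), attenuated by a tumor cfDNA fraction (0.5).
The plasma sample split (56 cases / 107 controls) mirrors a typical
discovery validation set. The plasma noise process of the real program is
not described anywhere, so `plasma_signal_rate` is a stand-in for
"detectable shedding", not a claim about the study's data; 0.6 was fixed
once as a plausible early-stage detectability and not tuned.

What the simulator does *not* emulate: batch effects, assay drift between
centers, age- or histology-dependent methylation, correlated markers
(detections are independent given the group), and the real plasma WGBS
background structure. Passing tests therefore demonstrate that the
pipeline's logic and statistics are correct under the stated generative
model — not that the assay would achieve these numbers on new clinical
material.

## Reconstructed count tables

`build_fixtures()` rebuilds the integer 2×2 tables behind the published
headline metrics from the printed "x of n" pairs and percentages, and
aborts if any reconstructed ratio rounds differently from its printed
value. Two printed inconsistencies are resolved in favor of internal
consistency: stage II sensitivity appears as both 86.69% and 86.49%
(96/111 = 86.49% is consistent with the stage totals summing to 548
detected cases), and stage III as both 89.70% and 89.71%
(183/204 = 89.71%). The overall specificity is reported both ways the
source computes it: 562/590 = 95.25% over benign + healthy controls, and
713/788 = 90.48% with the other-cancer controls folded in — the latter is
the denominator under which the published Youden index (0.76) is
recovered. The model-verification table is derived by brute force over
the true-positive count given its margins (92 cases / 205 controls) and
printed accuracy (95.29%): several candidates round κ to 0.89, so the
table with κ closest to 0.89 is taken ({85, 7, 7, 198}, κ = 0.8898). The
treatment-monitoring pairs reproduce the printed counts (29 of 32
post-operative negatives, three non-decliners, one of them a
pre-operative false negative) with synthetic score values, since no
individual scores are published.

## Problem sizes and determinism

All simulations in the test suite and analysis scripts use fixed seeds;
the generators are byte-identical under identical seed and spec. The
repeated-simulation checks use 100 seeds for the discovery screen
(500 regions, 30 vs 30 samples) and 200 seeds for the stage-sensitivity
calibration (641 cancer cases per replicate), sizes at which binomial
Monte-Carlo error is well below the tested margins. Degenerate inputs are
defined rather than accidental: empty cohorts return empty frames, zero
denominators give NA metrics, all-zero paired differences are flagged
untestable, and degenerate κ marginals return NA.

## Worked example

```{r example, eval = FALSE}
library(mdmpanel)

# reconstructed clinical table -> headline metrics
fx <- build_fixtures()
panel_metrics(fx$clinical_overall)
kappa_agreement(fx$clinical_overall)$kappa        # 0.80
specificity_with_other_cancers(fx)$youden_j       # 0.76

# simulate a calibrated cohort and push it through the caller
co <- generate_qmsp_cohort(cohort_spec(seed = 1))
calls <- call_cohort(co)
confusion(co$truth, calls$panel_call)
```

## Known limitations

* The published AUCs (0.947/0.948 model verification; 0.904 clinical) are
  not reproducible without the study's raw per-sample Ct values; the
  package substitutes property-based checks of its ROC/AUC implementation
  and a simulated cohort whose risk-score AUC lands in the same regime.
* Marker identities are labels only; no genome annotation is attempted,
  and regions are taken as given (no per-CpG smoothing or segmentation).
* Calibration inverts the OR rule assuming independent markers; real
  marker correlations would lower panel sensitivity at fixed per-marker
  rates.
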