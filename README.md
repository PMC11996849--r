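# mdmpanel

Plasma cell-free DNA (cfDNA) methylation biomarkers for early detection of
esophageal cancer: marker discovery from region-level methylation
matrices, interpretation of quantitative methylation-specific PCR (qMSP)
panel readouts, and full diagnostic-performance evaluation. The package is
aimed at computational biologists and biostatisticians building or
auditing methylated-DNA-marker (MDM) screening panels; every stage runs on
synthetic cohorts and on count tables reconstructed from a published
three-marker (Septin9 / Epo / MT-1A analog) clinical program, so no
external data are required.

## What it computes

**Discovery.** Candidate regions are screened from tumor vs
adjacent-normal tissue with a white-blood-cell background filter:

- adjusted *P* < 1×10⁻² (Wilcoxon rank-sum, Benjamini–Hochberg by
  default),
- Δ<sub>T2N</sub> = β̄<sub>tumor</sub> − β̄<sub>adjacent</sub> > 0.1,
- mean β<sub>WBC</sub> < 0.1.

Plasma signals are binarized by the one-hot transform — per-region
threshold at the 95th percentile of cancer-free control plasma, strict
comparison — and a panel is selected by ridge logistic regression on the
one-hot signals. Probe intervals from two array platforms are matched
when they overlap or lie ≤ 150 bp apart.

**Calling.** A qMSP record is valid iff ACTB reference Ct ≤ 34.8 and
cfDNA ≥ 0.9 ng/mL. A marker is positive iff it amplified at Ct ≤ its
cutoff; the panel is combined by the parallel (OR) rule. The methylation
risk score is 45 − ΔCt (ΔCt = marker Ct − ACTB Ct, undetected at the
45-cycle ceiling, panel = max over markers).

**Evaluation.** Sensitivity, specificity, PPV, NPV, accuracy, Youden's
J = sens + spec − 1, Cohen's κ with Fleiss-SE CI, Wilson / Wald /
Clopper–Pearson binomial intervals, empirical ROC with trapezoidal AUC
(= Mann–Whitney concordance), stratified reports, and paired Wilcoxon
signed-rank pre/post tests.

## Worked example

```r
library(mdmpanel)

# reconstructed clinical validation table (641 cancer vs 590 controls)
fx <- build_fixtures()
panel_metrics(fx$clinical_overall)[, 1:6]
#>        metric estimate  lower  upper    x    n
#> 1 sensitivity   0.8549 0.8255 0.8801  548  641
#> 2 specificity   0.9525 0.9323 0.9670  562  590
#> 3         ppv   0.9514 0.9306 0.9662  548  576
#> 4         npv   0.8580 0.8292 0.8827  562  655
#> 5    accuracy   0.9017 0.8838 0.9171 1110 1231
kappa_agreement(fx$clinical_overall)$kappa   # 0.8039 -> prints as 0.80
specificity_with_other_cancers(fx)$youden_j  # 0.7597 -> 0.76

# simulate a cohort calibrated to the observed per-stage panel rates,
# then call it with the default caller (ACTB gate, OR rule)
co <- generate_qmsp_cohort(cohort_spec(seed = 1))
calls <- call_cohort(co)
confusion(co$truth, calls$panel_call)
#>      call
#> truth pos neg
#>   pos 548  93
#>   neg  69 719
```

The simulated confusion matrix lands on the clinical table's margins
because the generator's detection probabilities are solved from the
observed OR-rule panel rates, p = 1 − (1 − s)^(1/3) per marker.

## Analysis workflow

Numbered drivers under `analysis/` run the whole pipeline on synthetic
data and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R    # discovery matrix + qMSP cohort + fixtures
Rscript analysis/02_discovery.R   # DMR screen, one-hot, panel selection
Rscript analysis/03_calling.R     # QC gate, marker calls, OR vs logistic
Rscript analysis/04_evaluation.R  # metrics on fixtures and simulation
```

## Scope

Region-level data only (no read alignment, per-CpG smoothing, or array
normalization); no downloading of the original cohorts; conventional
protein tumor markers appear only as published comparison constants. See
`vignettes/methylation-panel-methods.Rmd` for the model, parameter
choices, generator assumptions, and known limitations.
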