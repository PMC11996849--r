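#!/usr/bin/env Rscript
# Generate the two synthetic datasets the downstream analyses run on:
# a discovery-phase methylation matrix (tissue + WBC + plasma) and a
# clinical-style qMSP cohort calibrated to the observed per-group panel
# positivity rates. Everything is written as plain text under results/.

suppressPackageStartupMessages(library(mdmpanel))
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)
seed <- 20260929L

## Discovery-phase matrix: 500 regions, 10 planted hypermethylated DMRs,
## 30 tumor/adjacent pairs, 20 WBC, 56 case + 107 control plasma samples
## (the plasma split mirrors a typical discovery validation set).
dspec <- discovery_spec(seed = seed)
disc <- generate_discovery_data(dspec)
write_methyl_matrix(disc$matrix,
                    "results/data/discovery_matrix.tsv",
                    "results/data/discovery_regions.bed",
                    "results/data/discovery_samples.csv")
writeLines(disc$planted, "results/data/planted_regions.txt")
cat("discovery matrix:", nrow(disc$matrix$values), "regions x",
    ncol(disc$matrix$values), "samples;", length(disc$planted),
    "planted DMRs\n")

## Clinical-style qMSP cohort: 1,429 participants (641 cancer across
## stages 0-IV + unknown, 590 benign/healthy controls, 198 other
## cancers), detection probabilities solved from the observed OR-rule
## panel rates.
cspec <- cohort_spec(seed = seed)
cohort <- generate_qmsp_cohort(cspec)
write_qmsp_cohort(cohort, "results/data/qmsp_cohort.csv")
cat("qMSP cohort:", nrow(cohort), "participants;",
    sum(cohort$truth == "positive"), "cancer cases\n")

## Fixture count tables reconstructed from the printed clinical summary
write_fixtures(build_fixtures(), "results/data/fixtures.json")
cat("fixtures written to results/data/fixtures.json\n")
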