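#!/usr/bin/env Rscript
# Marker discovery on the simulated matrix from 01_simulate.R: screen
# hypermethylated regions (tumor vs adjacent, WBC background filter),
# apply the one-hot plasma transform against the control-derived 95th
# percentile, and select a 6-region panel by ridge logistic regression.

suppressPackageStartupMessages(library(mdmpanel))
dir.create("results", showWarnings = FALSE)

m <- read_methyl_matrix("results/data/discovery_matrix.tsv",
                        "results/data/discovery_regions.bed",
                        "results/data/discovery_samples.csv")
planted <- readLines("results/data/planted_regions.txt")

## Step 1: tissue screen (adjusted p < 1e-2, delta > 0.1, WBC < 0.1)
res <- screen_dmrs(m)
write_metrics_tsv(res, "results/dmr_screen.tsv")
passed <- res$region[res$pass_overall]
cat(sum(res$pass_overall), "regions pass the screen;",
    sum(passed %in% planted), "of", length(planted),
    "planted DMRs recovered\n")

## Step 2: one-hot plasma transform at the control 95th percentile
## (plasma samples only; tissue and WBC play no part in this step)
plasma <- subset_samples(m, m$samples$sample_id[
  m$samples$group %in% c("plasma_case", "plasma_control")])
ctrl_ids <- plasma$samples$sample_id[
  plasma$samples$group == "plasma_control"]
oh <- onehot_transform(plasma, ctrl_ids)
ctrl_rate <- rowMeans(oh$detected[, plasma$samples$sample_id %in% ctrl_ids])
cat("max per-region control detection rate:",
    round(max(ctrl_rate), 4), "(budget 0.05 + 1/n)\n")

## Step 3: panel selection among screened regions
labels <- stats::setNames(
  as.integer(plasma$samples$group == "plasma_case"),
  plasma$samples$sample_id)
p_adj <- stats::setNames(res$p_adj, res$region)
model <- select_markers(oh, labels, k = 6, candidate_regions = passed,
                        p_adj = p_adj)
cat("selected panel:", paste(model$selected_regions, collapse = ", "), "\n")
cat(sum(model$selected_regions %in% planted), "of 6 selected regions are",
    "planted DMRs\n")
pr <- predict(model, oh)
auc <- roc_curve(pr, ifelse(plasma$samples$group == "plasma_case",
                            "positive", "negative"))$auc
cat("in-sample plasma AUC of the selected panel:", round(auc, 3), "\n")
write_metrics_json(list(selected_regions = model$selected_regions,
                        n_pass = sum(res$pass_overall),
                        n_planted_recovered = sum(passed %in% planted),
                        plasma_auc = auc),
                   "results/discovery_summary.json")
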