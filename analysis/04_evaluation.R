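#!/usr/bin/env Rscript
# Diagnostic-performance evaluation, twice over:
#  (a) on the reconstructed clinical count tables — these reproduce the
#      published headline metrics exactly, and
#  (b) on the simulated cohort's calls from 03_calling.R — these agree
#      with (a) up to binomial noise, which is the end-to-end check that
#      simulator, caller and evaluator are mutually consistent.

suppressPackageStartupMessages(library(mdmpanel))

fx <- build_fixtures()

## (a) fixture-based metrics
m <- panel_metrics(fx$clinical_overall)
write_metrics_tsv(m, "results/clinical_metrics.tsv")
k <- kappa_agreement(fx$clinical_overall)
sw <- specificity_with_other_cancers(fx)
cat(sprintf("clinical cohort: sens %.2f%%, spec %.2f%%, PPV %.2f%%, NPV %.2f%%, accuracy %.2f%%\n",
            100 * m$estimate[m$metric == "sensitivity"],
            100 * m$estimate[m$metric == "specificity"],
            100 * m$estimate[m$metric == "ppv"],
            100 * m$estimate[m$metric == "npv"],
            100 * m$estimate[m$metric == "accuracy"]))
cat(sprintf("kappa %.2f (95%% CI %.2f-%.2f); Youden J %.2f with other cancers folded in (spec %.2f%%)\n",
            k$kappa, k$lower, k$upper, sw$youden_j, 100 * sw$specificity))

## (b) simulated-cohort metrics through the same evaluator
cohort <- read_qmsp_cohort("results/data/qmsp_cohort.csv")
calls <- read_calls("results/panel_calls.csv")
core <- cohort$truth == "positive" | cohort$group %in% c("benign", "healthy")
cc <- confusion(cohort$truth[core], calls$panel_call[core])
ms <- panel_metrics(cc)
cat(sprintf("simulated cohort: sens %.2f%%, spec %.2f%% (benign+healthy controls)\n",
            100 * ms$estimate[ms$metric == "sensitivity"],
            100 * ms$estimate[ms$metric == "specificity"]))
stage_rep <- stratified_report(cohort$truth[cohort$truth == "positive"],
                               calls$panel_call[cohort$truth == "positive"],
                               cohort$stage[cohort$truth == "positive"])
write_metrics_tsv(stage_rep, "results/simulated_stage_sensitivity.tsv")
cat("simulated per-stage sensitivity vs calibration target:\n")
st <- fx$stage_tp
for (s in c("0", "I", "II", "III", "IV")) {
  cat(sprintf("  stage %-7s %.2f%%  (target %.2f%%)\n", s,
              100 * stage_rep$sensitivity[stage_rep$stratum == s],
              100 * st$tp[st$stage == s] / st$n[st$stage == s]))
}

## treatment monitoring on the reconstructed pre/post pairs
pp <- fx$post_op_pairs
mon <- paired_pre_post(pp$pre_score, pp$post_score)
cat(sprintf("treatment monitoring: %d/%d post-operative negatives (%.1f%%), signed-rank p = %.2g\n",
            sum(pp$post_call == "negative"), nrow(pp),
            100 * mean(pp$post_call == "negative"), mon$p_value))
write_metrics_json(list(
  kappa = k$kappa, youden_j = sw$youden_j,
  sim_sensitivity = ms$estimate[ms$metric == "sensitivity"],
  sim_specificity = ms$estimate[ms$metric == "specificity"],
  postop_negative_rate = mean(pp$post_call == "negative"),
  postop_p = mon$p_value), "results/evaluation_summary.json")
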