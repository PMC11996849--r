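# tiny hand-built cohort: 2 cases with strong amplification, 2 clean
# controls, 1 QC failure
tiny_cohort <- function() {
  data.frame(
    sample_id = paste0("s", 1:5),
    group = c("ec_stage1", "ec_stage3", "healthy", "healthy", "benign"),
    stage = c("I", "III", NA, NA, NA),
    truth = c("positive", "positive", "negative", "negative", "negative"),
    actb_ct = c(28, 30, 29, 31, 36),
    ct_Septin9 = c(30, NA, NA, NA, NA),
    ct_Epo = c(NA, 33, NA, NA, NA),
    ct_MT1A = c(35, 34, NA, NA, NA),
    cfdna_ng_ml = c(5, 4, 6, 3, 5),
    stringsAsFactors = FALSE
  )
}

# brute-force AUC: concordance over all case-control pairs, ties half
pairwise_auc <- function(scores, truth, positive = "positive") {
  cs <- scores[truth == positive]
  ns <- scores[truth != positive]
  tot <- 0
  for (x in cs) for (y in ns) {
    tot <- tot + if (x > y) 1 else if (x == y) 0.5 else 0
  }
  tot / (length(cs) * length(ns))
}

# methyl_matrix with explicit values for threshold tests
small_plasma_matrix <- function(values, groups) {
  n_reg <- nrow(values)
  regions <- data.frame(chrom = "chr1",
                        start = (seq_len(n_reg) - 1L) * 100L,
                        end = (seq_len(n_reg) - 1L) * 100L + 50L)
  samples <- data.frame(sample_id = paste0("p", seq_len(ncol(values))),
                        group = groups, stringsAsFactors = FALSE)
  methyl_matrix(regions, values, samples)
}
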