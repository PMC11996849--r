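test_that("confusion counts partition samples and handle no_call", {
  truth <- c(rep("positive", 6), rep("negative", 4))
  expect_equal(confusion(truth, truth)[c("tp", "fp", "fn", "tn")],
               list(tp = 6L, fp = 0L, fn = 0L, tn = 4L))
  calls <- c("positive", "negative", "no_call", "positive", "positive",
             "negative", "negative", "positive", "no_call", "negative")
  cc <- confusion(truth, calls)
  expect_equal(cc$tp + cc$fp + cc$fn + cc$tn, 8)
  expect_equal(attr(cc, "n_no_call"), 2)
  expect_error(confusion(truth, calls[-1]), "equal length")
  expect_warning(cc0 <- confusion("positive", "no_call"), "no_call")
  expect_equal(cc0$tp + cc0$fp + cc0$fn + cc0$tn, 0)
})

test_that("metrics reproduce the printed clinical percentages", {
  cc <- confusion_counts(tp = 548, fp = 28, fn = 93, tn = 562)
  m <- panel_metrics(cc)
  g <- function(met) m$estimate[m$metric == met]
  expect_equal(as_percent(g("ppv")), 95.14)
  expect_equal(as_percent(g("npv")), 85.80)
  expect_equal(as_percent(g("accuracy")), 90.17)
  expect_equal(as_percent(g("sensitivity")), 85.49)
  expect_equal(as_percent(g("specificity")), 95.25)
  # diagnosed-group table
  m2 <- panel_metrics(confusion_counts(tp = 219, fp = 8, fn = 38, tn = 269))
  expect_equal(as_percent(m2$estimate[m2$metric == "ppv"]), 96.48)
  expect_equal(as_percent(m2$estimate[m2$metric == "npv"]), 87.62)
})

test_that("zero denominators give NA metrics, not zeros", {
  m <- panel_metrics(confusion_counts(0, 0, 0, 0))
  expect_true(all(is.na(m$estimate)))
  m2 <- panel_metrics(confusion_counts(tp = 3, fp = 0, fn = 1, tn = 0))
  expect_true(is.na(m2$estimate[m2$metric == "specificity"]))
  expect_false(is.na(m2$estimate[m2$metric == "sensitivity"]))
})

test_that("metrics are invariant to sample order", {
  set.seed(11)
  truth <- sample(c("positive", "negative"), 40, replace = TRUE)
  calls <- sample(c("positive", "negative"), 40, replace = TRUE)
  perm <- sample(40)
  expect_equal(panel_metrics(confusion(truth, calls)),
               panel_metrics(confusion(truth[perm], calls[perm])))
})

test_that("kappa matches the printed agreement values and edge cases", {
  expect_equal(round_half_up(
    kappa_agreement(confusion_counts(548, 28, 93, 562))$kappa), 0.80)
  expect_equal(round_half_up(
    kappa_agreement(confusion_counts(85, 7, 7, 198))$kappa), 0.89)
  expect_equal(kappa_agreement(confusion_counts(10, 0, 0, 15))$kappa, 1)
  # one-sided prediction: agreement is exactly chance
  expect_equal(kappa_agreement(confusion_counts(10, 15, 0, 0))$kappa, 0)
  # degenerate marginals
  expect_true(is.na(kappa_agreement(confusion_counts(10, 0, 0, 0))$kappa))
})

test_that("kappa is symmetric under simultaneous label swap and has a CI", {
  cc <- confusion_counts(85, 7, 7, 198)
  swapped <- confusion_counts(tp = 198, fp = 7, fn = 7, tn = 85)
  k1 <- kappa_agreement(cc)
  expect_equal(k1$kappa, kappa_agreement(swapped)$kappa)
  expect_lt(k1$lower, k1$kappa)
  expect_gt(k1$upper, k1$kappa)
})

test_that("Wilson interval reproduces printed CIs", {
  expect_equal(round(ci_wilson(548, 641), 4), c(0.8255, 0.8801))
  ci <- ci_wilson(28, 28)
  expect_equal(round(ci[1], 4), 0.8794)
  expect_equal(ci[2], 1)
  expect_equal(ci_wilson(0, 28)[1], 0)
})

test_that("Wald interval reproduces the printed stage-0 CI", {
  expect_equal(round(ci_wald(18, 32), 4), c(0.3906, 0.7344))
  # symmetry about 0.5 when x = n/2
  ci <- ci_wald(25, 50)
  expect_equal(ci[1] + ci[2], 1)
  # clamping
  expect_equal(ci_wald(29, 30)[2], 1)
  expect_gt(ci_wald(29, 30, clamp = FALSE)[2], 1)
})

test_that("Clopper-Pearson matches binom.test and the printed bound", {
  expect_equal(round(ci_clopper_pearson(30, 30)[1], 4), 0.8843)
  for (case in list(c(5, 20), c(0, 13), c(13, 13), c(17, 40))) {
    expect_equal(ci_clopper_pearson(case[1], case[2]),
                 as.numeric(binom.test(case[1], case[2])$conf.int),
                 tolerance = 1e-10)
  }
})

test_that("interval families are ordered as theory predicts", {
  set.seed(4)
  for (i in 1:20) {
    n <- sample(10:200, 1)
    x <- sample(0:n, 1)
    w <- ci_wilson(x, n)
    cp <- ci_clopper_pearson(x, n)
    expect_true(all(w >= 0 & w <= 1) && all(cp >= 0 & cp <= 1))
    # exact interval contains the point estimate
    expect_true(cp[1] <= x / n + 1e-12 && cp[2] >= x / n - 1e-12)
    expect_true(w[1] <= x / n + 1e-12 && w[2] >= x / n - 1e-12)
  }
  expect_error(ci_wilson(5, 0), "n > 0")
  expect_error(ci_wilson(-1, 10), "0 <= x")
})

test_that("ROC endpoints, AUC and tie handling follow the empirical curve", {
  truth <- c(rep("positive", 3), rep("negative", 3))
  r <- roc_curve(c(5, 4, 3, 2, 1, 0), truth)
  expect_equal(r$auc, 1)
  expect_equal(r$points$fpr[1], 0)
  expect_equal(r$points$tpr[1], 0)
  expect_equal(r$points$fpr[nrow(r$points)], 1)
  expect_equal(r$points$tpr[nrow(r$points)], 1)
  expect_equal(roc_curve(rep(1, 6), truth)$auc, 0.5)
  expect_error(roc_curve(1:3, rep("positive", 3)), "both classes")
})

test_that("trapezoidal AUC equals brute-force pairwise concordance", {
  # 6-sample worked set with a tie across classes
  scores <- c(0.9, 0.8, 0.8, 0.4, 0.3, 0.1)
  truth <- c("positive", "positive", "negative", "positive", "negative",
             "negative")
  expect_equal(roc_curve(scores, truth)$auc, pairwise_auc(scores, truth))
  set.seed(21)
  for (i in 1:25) {
    n <- sample(4:20, 1)
    truth <- c("positive", "negative",
               sample(c("positive", "negative"), n - 2, replace = TRUE))
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
    expect_equal(roc_curve(scores, truth)$auc, pairwise_auc(scores, truth))
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(8)
  scores <- rnorm(40)
  truth <- rep(c("positive", "negative"), 20)
  base <- roc_curve(scores, truth)$auc
  expect_equal(roc_curve(exp(scores), truth)$auc, base)
  expect_equal(roc_curve(3 * scores - 7, truth)$auc, base)
  expect_equal(roc_curve(atan(scores), truth)$auc, base)
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(13)
  scores <- c(rnorm(25, 1), rnorm(25))
  truth <- rep(c("positive", "negative"), each = 25)
  ours <- roc_curve(scores, truth)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = truth, predictor = scores, levels = c("negative", "positive"),
    direction = "<", quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("stratified report sums to the overall table and keeps empty strata", {
  fx <- build_fixtures()
  # expand the per-stage fixture into labelled cases
  truth <- rep("positive", sum(fx$stage_tp$n))
  calls <- unlist(mapply(function(tp, n) {
    c(rep("positive", tp), rep("negative", n - tp))
  }, fx$stage_tp$tp, fx$stage_tp$n, SIMPLIFY = FALSE))
  strata <- rep(fx$stage_tp$stage, fx$stage_tp$n)
  rep <- stratified_report(truth, calls, strata)
  by_stage <- rep[match(c("0", "I", "II", "III", "IV"), rep$stratum), ]
  expect_equal(as_percent(by_stage$sensitivity),
               c(56.25, 77.36, 86.49, 89.71, 94.02))
  expect_equal(sum(rep$tp[rep$stratum != "overall"]),
               rep$tp[rep$stratum == "overall"])
  # single stratum equals overall
  one <- stratified_report(truth, calls, rep("all", length(truth)))
  expect_equal(one$sensitivity[1], one$sensitivity[2])
  # empty stratum flagged, not dropped
  withempty <- stratified_report(truth, calls,
                                 factor(strata, levels = c(fx$stage_tp$stage,
                                                           "ghost")))
  expect_true(withempty$empty[withempty$stratum == "ghost"])
})

test_that("other-cancer strata reproduce printed specificities", {
  fx <- build_fixtures()
  truth <- rep("negative", sum(fx$other_cancer_tn$n))
  calls <- unlist(mapply(function(tn, n) {
    c(rep("negative", tn), rep("positive", n - tn))
  }, fx$other_cancer_tn$tn, fx$other_cancer_tn$n, SIMPLIFY = FALSE))
  strata <- rep(fx$other_cancer_tn$type, fx$other_cancer_tn$n)
  rep <- stratified_report(truth, calls, strata)
  expect_equal(
    as_percent(rep$specificity[match(c("colorectal", "gastric"),
                                     rep$stratum)]),
    c(56.86, 70.00))
  expect_equal(
    rep$specificity[match(c("lung", "breast"), rep$stratum)], c(1, 1))
})

test_that("paired Wilcoxon flags degenerate input and detects uniform drops", {
  pre <- seq(30, 45, length.out = 32)
  same <- paired_pre_post(pre, pre)
  expect_true(same$degenerate)
  expect_true(is.na(same$p_value))
  drop <- paired_pre_post(pre, pre - 5)
  expect_lt(drop$p_value, 0.001)
  expect_equal(drop$n_decreased, 32L)
  expect_error(paired_pre_post(1:5, 1:4), "equal length")
  # unpaired routing
  un <- paired_pre_post(rnorm(10), rnorm(12, 3), paired = FALSE)
  expect_equal(un$method, "wilcoxon rank-sum")
})

test_that("half-up rounding matches printed-percentage conventions", {
  expect_equal(round_half_up(0.125, 2), 0.13)   # base round() gives 0.12
  expect_equal(round_half_up(0.845, 2), 0.85)
  expect_equal(as_percent(548 / 641), 85.49)
  expect_equal(round_half_up(-0.125, 2), -0.13)
})
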