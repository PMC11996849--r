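probes <- function(...) {
  rows <- list(...)
  data.frame(probe_id = vapply(rows, `[[`, "", 1),
             chrom = vapply(rows, `[[`, "", 2),
             start = as.integer(vapply(rows, `[[`, "", 3)),
             end = as.integer(vapply(rows, `[[`, "", 4)),
             stringsAsFactors = FALSE)
}

test_that("probe matching honours overlap and the 150 bp gap boundary", {
  a <- probes(c("a1", "chr1", "100", "250"))
  # gap of exactly 150 bp matches, 151 does not
  expect_equal(nrow(harmonize_probes(
    a, probes(c("b1", "chr1", "400", "500")))), 1)
  expect_equal(nrow(harmonize_probes(
    a, probes(c("b1", "chr1", "401", "500")))), 0)
  # overlapping intervals match
  expect_equal(nrow(harmonize_probes(
    a, probes(c("b1", "chr1", "200", "300")))), 1)
  # different chromosome never matches
  expect_equal(nrow(harmonize_probes(
    a, probes(c("b1", "chr2", "200", "300")))), 0)
  expect_error(harmonize_probes(
    a, probes(c("b1", "chr1", "300", "200"))), "b1")
})

test_that("probe matching is symmetric and admits multiple partners", {
  a <- probes(c("a1", "chr1", "100", "250"), c("a2", "chr1", "900", "1000"),
              c("a3", "chr2", "0", "50"))
  b <- probes(c("b1", "chr1", "200", "300"), c("b2", "chr1", "300", "420"),
              c("b3", "chr2", "10", "40"))
  ab <- harmonize_probes(a, b)
  ba <- harmonize_probes(b, a)
  expect_setequal(paste(ab$probe_a, ab$probe_b),
                  paste(ba$probe_b, ba$probe_a))
  expect_equal(sum(ab$probe_a == "a1"), 2)  # a1 pairs with b1 and b2
})

test_that("DMR screen isolates each criterion and recovers a planted region", {
  set.seed(31)
  d <- generate_discovery_data(discovery_spec(n_regions = 200, n_dmr = 5,
                                              seed = 31))
  res <- screen_dmrs(d$matrix)
  planted <- res[res$region %in% d$planted, ]
  expect_true(all(planted$pass_overall))
  expect_true(all(planted$p_adj < 1e-2))
  expect_true(all(planted$delta_t2n > 0.1))
  expect_true(all(planted$mean_wbc < 0.1))
  # background regions share the tissue mean everywhere: no pass
  expect_equal(sum(res$pass_overall), 5)
  # results sorted by p_adj
  expect_true(!is.unsorted(res$p_adj, na.rm = TRUE))
})

test_that("a high WBC background vetoes an otherwise perfect region", {
  set.seed(7)
  d <- generate_discovery_data(discovery_spec(n_regions = 100, n_dmr = 4,
                                              wbc_beta = 0.2, seed = 7))
  res <- screen_dmrs(d$matrix)
  planted <- res[res$region %in% d$planted, ]
  expect_true(all(planted$pass_p))
  expect_true(all(planted$pass_delta))
  expect_false(any(planted$pass_wbc))
  expect_false(any(planted$pass_overall))
})

test_that("null data produces no overall passes", {
  set.seed(12)
  d <- generate_discovery_data(discovery_spec(n_regions = 300, n_dmr = 10,
                                              delta_planted = 0, seed = 12))
  res <- screen_dmrs(d$matrix)
  expect_equal(sum(res$pass_overall), 0)
})

test_that("adjusted p dominates raw p and the pass set shrinks with stricter thresholds", {
  set.seed(9)
  d <- generate_discovery_data(discovery_spec(n_regions = 150, n_dmr = 8,
                                              seed = 9))
  res <- screen_dmrs(d$matrix)
  ok <- !res$untestable
  expect_true(all(res$p_adj[ok] >= res$p_raw[ok] - 1e-12))
  strict_alpha <- screen_dmrs(d$matrix, alpha = 1e-4)
  strict_delta <- screen_dmrs(d$matrix, min_delta = 0.3)
  expect_true(all(strict_alpha$region[strict_alpha$pass_overall] %in%
                    res$region[res$pass_overall]))
  expect_true(all(strict_delta$region[strict_delta$pass_overall] %in%
                    res$region[res$pass_overall]))
  # Bonferroni is at least as conservative as BH
  bonf <- screen_dmrs(d$matrix, adjust = "bonferroni")
  expect_true(all(bonf$p_adj[ok] >= res$p_adj[ok] - 1e-12))
  expect_error(screen_dmrs(methyl_matrix(
    data.frame(chrom = "chr1", start = 0L, end = 10L),
    matrix(0.5, 1, 2),
    data.frame(sample_id = c("x", "y"), group = c("tumor", "tumor")))),
    "adjacent")
})

test_that("missing values are excluded pairwise and dead regions flagged", {
  set.seed(2)
  vals <- matrix(runif(3 * 8), 3, 8)
  vals[2, 1:6] <- NA                # untestable: < 2 tumor values
  vals[3, 1] <- NA                  # still testable
  m <- small_plasma_matrix(vals, c(rep("tumor", 4), rep("adjacent", 4)))
  res <- screen_dmrs(m)
  keys <- region_key(m$regions)
  expect_true(res$untestable[res$region == keys[2]])
  expect_true(is.na(res$p_adj[res$region == keys[2]]))
  expect_false(res$untestable[res$region == keys[3]])
})

test_that("one-hot threshold is the type-7 95th percentile of controls", {
  ctrl_vals <- seq(0.01, 0.10, length.out = 100)
  vals <- rbind(c(ctrl_vals, 0.15, 0.05))
  m <- small_plasma_matrix(vals, c(rep("plasma_control", 100),
                                   "plasma_case", "plasma_case"))
  oh <- onehot_transform(m, m$samples$sample_id[1:100])
  expect_equal(unname(oh$thresholds[1]),
               unname(quantile(ctrl_vals, 0.95, type = 7)))
  expect_equal(unname(oh$signals[1, 101]), 0.15)  # above threshold: kept
  expect_equal(unname(oh$signals[1, 102]), 0)     # below: zeroed
})

test_that("one-hot detection is strict and idempotent, controls capped near 5%", {
  # degenerate: all controls equal c; a level at c is NOT detected
  vals <- rbind(rep(0.3, 25), rep(0.3, 25))
  vals[1, 25] <- 0.3               # case at threshold
  vals[2, 25] <- 0.31              # case above threshold
  m <- small_plasma_matrix(vals, c(rep("plasma_control", 24), "plasma_case"))
  oh <- onehot_transform(m, m$samples$sample_id[1:24])
  expect_equal(unname(oh$signals[1, 25]), 0)
  expect_equal(unname(oh$signals[2, 25]), 0.31)
  # random matrix: control detection rate bounded by construction
  set.seed(5)
  vals2 <- matrix(runif(50 * 60), 50, 60)
  m2 <- small_plasma_matrix(vals2, rep(c("plasma_control", "plasma_case"),
                                       each = 30))
  ctrl_ids <- m2$samples$sample_id[1:30]
  oh2 <- onehot_transform(m2, ctrl_ids)
  rate <- rowMeans(oh2$detected[, 1:30])
  expect_true(all(rate <= 0.05 + 1 / 30 + 1e-12))
  # nonzero signals equal the input levels exactly
  expect_true(all((oh2$signals == vals2 | oh2$signals == 0)))
  # idempotence on the nonzero pattern: thresholding detected signals
  # again never invents a new detection
  m3 <- small_plasma_matrix(oh2$signals, m2$samples$group)
  oh3 <- onehot_transform(m3, ctrl_ids)
  expect_true(all(oh3$detected == (oh3$signals > 0)))
  expect_true(all(which(oh3$detected) %in% which(oh2$detected)))
  expect_error(onehot_transform(m2, character(0)), "empty")
  expect_warning(onehot_transform(m2, ctrl_ids[1:5]), "20 controls")
})

test_that("marker selection finds a perfect separator and planted regions", {
  set.seed(17)
  # one region perfectly separates cases and controls
  vals <- matrix(runif(20 * 40, 0, 0.05), 20, 40)
  vals[7, 21:40] <- runif(20, 0.5, 0.9)
  groups <- rep(c("plasma_control", "plasma_case"), each = 20)
  m <- small_plasma_matrix(vals, groups)
  oh <- onehot_transform(m, m$samples$sample_id[1:20])
  labels <- as.integer(groups == "plasma_case")
  mm <- select_markers(oh, labels, k = 1)
  expect_equal(mm$selected_regions, region_key(m$regions)[7])
  expect_error(select_markers(oh, labels, k = 10000), "exceeds")
  expect_error(select_markers(oh, rep(1, 40), k = 1), "both classes")
  # planted-signal recovery through the full discovery chain
  d <- generate_discovery_data(discovery_spec(seed = 17))
  res <- screen_dmrs(d$matrix)
  plasma <- subset_samples(d$matrix, d$matrix$samples$sample_id[
    d$matrix$samples$group %in% c("plasma_case", "plasma_control")])
  oh2 <- onehot_transform(plasma, plasma$samples$sample_id[
    plasma$samples$group == "plasma_control"])
  labs <- stats::setNames(
    as.integer(plasma$samples$group == "plasma_case"),
    plasma$samples$sample_id)
  mm2 <- select_markers(oh2, labs, k = 6,
                        candidate_regions = res$region[res$pass_overall])
  expect_gte(sum(mm2$selected_regions %in% d$planted), 5)
})

test_that("shuffled labels give a chance-level model", {
  d <- generate_discovery_data(discovery_spec(seed = 23))
  plasma <- subset_samples(d$matrix, d$matrix$samples$sample_id[
    d$matrix$samples$group %in% c("plasma_case", "plasma_control")])
  ctrl_ids <- plasma$samples$sample_id[
    plasma$samples$group == "plasma_control"]
  set.seed(23)
  # train on half the plasma samples with permuted labels, assess on rest
  perm_labels <- stats::setNames(
    sample(as.integer(plasma$samples$group == "plasma_case")),
    plasma$samples$sample_id)
  train <- sample(plasma$samples$sample_id,
                  nrow(plasma$samples) %/% 2)
  test_ids <- setdiff(plasma$samples$sample_id, train)
  oh_tr <- onehot_transform(subset_samples(plasma, train),
                            intersect(ctrl_ids, train))
  mm <- select_markers(oh_tr, perm_labels[train], k = 6)
  oh_te <- onehot_transform(subset_samples(plasma, test_ids),
                            intersect(ctrl_ids, test_ids))
  pr <- predict(mm, oh_te)
  truth <- ifelse(perm_labels[names(pr)] == 1, "positive", "negative")
  auc <- roc_curve(pr, truth)$auc
  expect_gte(auc, 0.4)
  expect_lte(auc, 0.6)
})
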