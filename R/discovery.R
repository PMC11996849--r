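#' Construct a region-by-sample methylation matrix
#'
#' The substrate of marker discovery: methylation levels (beta values in
#' \[0,1\], `NA` allowed) for a set of genomic regions across labelled
#' samples. Regions use 0-based half-open coordinates (BED convention).
#'
#' @param regions data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param values numeric matrix, regions x samples; rownames are region
#'   keys `"chrom:start-end"`.
#' @param samples data.frame with columns `sample_id`, `group`.
#' @return object of class `methyl_matrix`.
#' @export
methyl_matrix <- function(regions, values, samples) {
  stopifnot(is.data.frame(regions), is.matrix(values), is.data.frame(samples))
  if (!all(c("chrom", "start", "end") %in% names(regions))) {
    stop("regions needs chrom, start, end")
  }
  if (!all(c("sample_id", "group") %in% names(samples))) {
    stop("samples needs sample_id, group")
  }
  if (any(regions$start >= regions$end)) {
    bad <- which(regions$start >= regions$end)[1]
    stop("region ", bad, " has start >= end")
  }
  if (nrow(values) != nrow(regions) || ncol(values) != nrow(samples)) {
    stop("values must be ", nrow(regions), " regions x ", nrow(samples),
         " samples")
  }
  out_of_range <- which(!is.na(values) & (values < 0 | values > 1),
                        arr.ind = TRUE)
  if (nrow(out_of_range) > 0) {
    stop("methylation level outside [0,1] at region ", out_of_range[1, 1],
         ", sample ", out_of_range[1, 2])
  }
  rownames(values) <- region_key(regions)
  colnames(values) <- samples$sample_id
  structure(list(regions = regions, values = values, samples = samples),
            class = "methyl_matrix")
}

#' @export
print.methyl_matrix <- function(x, ...) {
  cat("methyl_matrix:", nrow(x$values), "regions x", ncol(x$values),
      "samples (groups:",
      paste(names(table(x$samples$group)), collapse = ", "), ")\n")
  invisible(x)
}

#' Region key string "chrom:start-end" (0-based half-open)
#' @param regions data.frame with chrom, start, end.
#' @export
region_key <- function(regions) {
  paste0(regions$chrom, ":", regions$start, "-", regions$end)
}

#' Restrict a methylation matrix to a subset of samples
#'
#' @param m `methyl_matrix`.
#' @param sample_ids ids to keep (order preserved as given).
#' @return `methyl_matrix` over the same regions.
#' @export
subset_samples <- function(m, sample_ids) {
  stopifnot(inherits(m, "methyl_matrix"))
  missing_ids <- setdiff(sample_ids, m$samples$sample_id)
  if (length(missing_ids) > 0) {
    stop("sample ids absent from matrix: ",
         paste(utils::head(missing_ids, 3), collapse = ", "))
  }
  idx <- match(sample_ids, m$samples$sample_id)
  methyl_matrix(m$regions, m$values[, idx, drop = FALSE],
                m$samples[idx, , drop = FALSE])
}

#' Match probes across two array platforms
#'
#' Pairs probe design intervals from two platforms when the intervals
#' overlap in genome coordinates or lie within `max_gap` base pairs of
#' each other on the same chromosome (gap measured end-to-start; a gap of
#' exactly `max_gap` matches). Symmetric: a probe may appear in several
#' pairs. Overlap resolution is delegated to GenomicRanges.
#'
#' @param a,b data.frames with columns `probe_id`, `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param max_gap maximum separating gap in bp (default 150).
#' @return data.frame with columns `probe_a`, `probe_b`.
#' @export
harmonize_probes <- function(a, b, max_gap = 150) {
  as_gr <- function(df, who) {
    need <- c("probe_id", "chrom", "start", "end")
    if (!all(need %in% names(df))) {
      stop("probe table ", who, " needs columns: ",
           paste(need, collapse = ", "))
    }
    bad <- which(is.na(df$start) | is.na(df$end) | df$start >= df$end |
                   is.na(df$chrom) | df$chrom == "")
    if (length(bad) > 0) {
      stop("malformed region for probe ", df$probe_id[bad[1]], " in ", who)
    }
    if (anyDuplicated(df$probe_id)) {
      stop("duplicate probe_id in ", who, ": ",
           df$probe_id[duplicated(df$probe_id)][1])
    }
    # BED half-open -> 1-based closed IRanges
    GenomicRanges::GRanges(df$chrom,
                           IRanges::IRanges(df$start + 1L, df$end))
  }
  gra <- as_gr(a, "a")
  grb <- as_gr(b, "b")
  # platforms may cover different chromosome sets; the seqlevel-union
  # warning is expected and meaningless here
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(gra, grb, maxgap = max_gap))
  data.frame(probe_a = a$probe_id[S4Vectors::queryHits(hits)],
             probe_b = b$probe_id[S4Vectors::subjectHits(hits)],
             stringsAsFactors = FALSE)
}

#' Screen for cancer-specific hypermethylated regions
#'
#' Per region: a two-group test of tumor versus adjacent-normal
#' methylation levels, multiplicity-adjusted across all testable regions;
#' the tumor-minus-normal mean difference (delta_t2n); and the mean
#' white-blood-cell methylation (mean_wbc), the blood-background filter.
#' A region passes overall when all three criteria hold:
#' adjusted p < `alpha`, delta_t2n > `min_delta`, mean_wbc < `max_wbc`.
#' Missing values are excluded pairwise, never imputed; regions with
#' fewer than 2 usable values in either test group are flagged
#' `untestable` and excluded from the adjustment denominator.
#'
#' @param m `methyl_matrix` whose sample groups include `tumor`,
#'   `adjacent` and (optionally, for the background filter) `wbc`.
#' @param alpha adjusted-p threshold (default 1e-2).
#' @param min_delta minimum tumor-minus-normal difference (default 0.1).
#' @param max_wbc maximum WBC background level (default 0.1).
#' @param test `"wilcoxon"` (rank-sum, default) or `"t"` (Welch).
#' @param adjust `"BH"` (default) or `"bonferroni"`.
#' @return data.frame sorted by p_adj ascending (ties: |delta_t2n|
#'   descending): region, p_raw, p_adj, delta_t2n, mean_wbc, pass_p,
#'   pass_delta, pass_wbc, pass_overall, untestable.
#' @export
screen_dmrs <- function(m, alpha = 1e-2, min_delta = 0.1, max_wbc = 0.1,
                        test = c("wilcoxon", "t"),
                        adjust = c("BH", "bonferroni")) {
  stopifnot(inherits(m, "methyl_matrix"))
  test <- match.arg(test)
  adjust <- match.arg(adjust)
  grp <- m$samples$group
  for (g in c("tumor", "adjacent")) {
    if (!any(grp == g)) stop("group absent from matrix: ", g)
  }
  tum <- m$values[, grp == "tumor", drop = FALSE]
  adj <- m$values[, grp == "adjacent", drop = FALSE]
  wbc <- m$values[, grp == "wbc", drop = FALSE]
  n_reg <- nrow(m$values)
  p_raw <- rep(NA_real_, n_reg)
  delta <- rowMeans(tum, na.rm = TRUE) - rowMeans(adj, na.rm = TRUE)
  mean_wbc <- if (ncol(wbc) > 0) rowMeans(wbc, na.rm = TRUE)
              else rep(NA_real_, n_reg)
  testable <- rowSums(!is.na(tum)) >= 2 & rowSums(!is.na(adj)) >= 2
  for (i in which(testable)) {
    x <- tum[i, !is.na(tum[i, ])]
    y <- adj[i, !is.na(adj[i, ])]
    p_raw[i] <- if (test == "wilcoxon") {
      suppressWarnings(stats::wilcox.test(x, y, exact = FALSE)$p.value)
    } else {
      stats::t.test(x, y)$p.value
    }
  }
  p_adj <- rep(NA_real_, n_reg)
  p_adj[testable] <- stats::p.adjust(p_raw[testable], method = adjust)
  pass_p <- !is.na(p_adj) & p_adj < alpha
  pass_delta <- !is.na(delta) & delta > min_delta
  pass_wbc <- !is.na(mean_wbc) & mean_wbc < max_wbc
  out <- data.frame(region = rownames(m$values), p_raw = p_raw,
                    p_adj = p_adj, delta_t2n = delta, mean_wbc = mean_wbc,
                    pass_p = pass_p, pass_delta = pass_delta,
                    pass_wbc = pass_wbc,
                    pass_overall = pass_p & pass_delta & pass_wbc,
                    untestable = !testable, stringsAsFactors = FALSE)
  out <- out[order(out$p_adj, -abs(out$delta_t2n), na.last = TRUE), ]
  rownames(out) <- NULL
  out
}

#' One-hot transform of plasma methylation signals
#'
#' Plasma WGBS carries a strong background, so per-region signals are
#' binarized against a control-derived null: the detection threshold is
#' the 95th percentile (linear-interpolation quantile) of plasma levels
#' in cancer-free controls, targeting 95\% specificity by construction.
#' A level strictly above the threshold is "detected" and keeps its value;
#' anything at or below it becomes 0.
#'
#' @param plasma `methyl_matrix` of plasma samples.
#' @param control_ids sample ids defining the cancer-free null.
#' @param probs quantile defining the threshold (default 0.95).
#' @return object of class `onehot_matrix`: list with `thresholds`
#'   (per region), `signals` (region x sample; 0 or the original level)
#'   and `detected` (logical companion).
#' @export
onehot_transform <- function(plasma, control_ids, probs = 0.95) {
  stopifnot(inherits(plasma, "methyl_matrix"))
  ids <- plasma$samples$sample_id
  if (length(control_ids) == 0) stop("control set is empty")
  missing_ids <- setdiff(control_ids, ids)
  if (length(missing_ids) > 0) {
    stop("control ids absent from matrix: ",
         paste(utils::head(missing_ids, 3), collapse = ", "))
  }
  if (length(control_ids) < 20) {
    warning("fewer than 20 controls; the ", probs,
            " quantile threshold will be unstable")
  }
  ctrl <- plasma$values[, ids %in% control_ids, drop = FALSE]
  thresholds <- apply(ctrl, 1, stats::quantile, probs = probs,
                      na.rm = TRUE, type = 7, names = FALSE)
  detected <- sweep(plasma$values, 1, thresholds, ">")
  detected[is.na(detected)] <- FALSE
  signals <- ifelse(detected, plasma$values, 0)
  structure(list(thresholds = thresholds, signals = signals,
                 detected = detected, control_ids = control_ids,
                 samples = plasma$samples, regions = plasma$regions),
            class = "onehot_matrix")
}

#' Select a marker panel by regularized logistic regression
#'
#' Fits an L2-regularized (ridge) logistic model of case/control status on
#' the one-hot plasma signals of screened regions, ranks regions by the
#' absolute standardized coefficient (ties broken by adjusted p when
#' supplied), keeps the top `k`, and refits the ridge model on those `k`
#' alone. Ridge keeps coefficients finite under perfect separation.
#' Deterministic: fixed lambda, no internal CV.
#'
#' @param oh `onehot_matrix`.
#' @param labels named (by sample_id) or positional vector; TRUE/1 = case.
#' @param k target panel size.
#' @param candidate_regions optional subset of region keys to consider
#'   (typically the pass set of [screen_dmrs()]).
#' @param p_adj optional named vector of adjusted p-values for
#'   tie-breaking.
#' @param lambda ridge penalty.
#' @return object of class `marker_model`: list with `selected_regions`,
#'   `coefficients` (intercept + per-region, on the refit), `ranking`
#'   data.frame, and training metadata.
#' @export
select_markers <- function(oh, labels, k, candidate_regions = NULL,
                           p_adj = NULL, lambda = 0.01) {
  stopifnot(inherits(oh, "onehot_matrix"))
  x_all <- t(oh$signals)            # samples x regions
  if (!is.null(names(labels))) {
    labels <- labels[oh$samples$sample_id]
  }
  y <- as.integer(labels)
  if (length(y) != nrow(x_all)) stop("labels must cover every sample")
  if (length(unique(y)) < 2) stop("both classes must be present")
  keys <- rownames(oh$signals)
  if (!is.null(candidate_regions)) {
    keep <- keys %in% candidate_regions
    if (!any(keep)) stop("no candidate regions present in the matrix")
    x_all <- x_all[, keep, drop = FALSE]
    keys <- keys[keep]
  }
  if (k > length(keys)) {
    stop("k = ", k, " exceeds the ", length(keys), " available regions")
  }
  # drop zero-variance columns (unrankable; glmnet standardization breaks)
  sds <- apply(x_all, 2, stats::sd)
  informative <- sds > 0
  if (sum(informative) < k) {
    stop("only ", sum(informative), " regions carry any signal; k = ", k)
  }
  x <- x_all[, informative, drop = FALSE]
  keys_i <- keys[informative]
  fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                        lambda = lambda, standardize = TRUE)
  beta <- as.numeric(stats::coef(fit))[-1]
  std_beta <- abs(beta) * apply(x, 2, stats::sd)
  tie <- if (!is.null(p_adj)) {
    v <- p_adj[keys_i]
    v[is.na(v)] <- 1
    v
  } else rep(0, length(keys_i))
  ord <- order(-std_beta, tie)
  ranking <- data.frame(region = keys_i[ord],
                        std_coefficient = std_beta[ord],
                        coefficient = beta[ord],
                        stringsAsFactors = FALSE)
  sel <- ranking$region[seq_len(k)]
  xr <- x[, match(sel, keys_i), drop = FALSE]
  if (ncol(xr) == 1) {
    # glmnet requires >= 2 columns; a zero-variance pad gets coefficient 0
    xr <- cbind(xr, `.pad` = 0)
  }
  refit <- glmnet::glmnet(xr, y, family = "binomial", alpha = 0,
                          lambda = lambda, standardize = TRUE)
  co <- stats::coef(refit)
  coefficients <- stats::setNames(as.numeric(co), rownames(co))
  coefficients <- coefficients[names(coefficients) != ".pad"]
  structure(list(selected_regions = sel, coefficients = coefficients,
                 ranking = ranking, lambda = lambda,
                 n = nrow(x), n_case = sum(y == 1), n_control = sum(y == 0)),
            class = "marker_model")
}

#' Predict case probabilities from a fitted marker model
#'
#' @param object `marker_model` from [select_markers()].
#' @param oh `onehot_matrix` with the model's regions present.
#' @param ... unused.
#' @return named numeric vector of probabilities per sample.
#' @export
predict.marker_model <- function(object, oh, ...) {
  stopifnot(inherits(oh, "onehot_matrix"))
  x <- t(oh$signals[object$selected_regions, , drop = FALSE])
  eta <- object$coefficients[["(Intercept)"]] +
    as.numeric(x %*% object$coefficients[object$selected_regions])
  stats::setNames(stats::plogis(eta), oh$samples$sample_id)
}
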