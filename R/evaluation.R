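#' Build a 2x2 confusion table from truth and predicted labels
#'
#' Counts true/false positives and negatives for a binary diagnostic call.
#' Samples whose call is `"no_call"` are excluded from the counts (and
#' tallied in the `n_no_call` attribute) — a sample without a valid assay
#' result belongs in neither denominator.
#'
#' @param truth character/factor vector of reference labels.
#' @param calls character/factor vector of predicted labels, same length.
#' @param positive label treated as the positive (disease) class.
#' @param negative label treated as the negative class.
#' @param no_call label marking samples without a valid result.
#' @return object of class `confusion_counts`: list with integer fields
#'   `tp`, `fp`, `fn`, `tn` and attribute `n_no_call`.
#' @export
confusion <- function(truth, calls, positive = "positive",
                      negative = "negative", no_call = "no_call") {
  if (length(truth) != length(calls)) {
    stop("`truth` and `calls` must have equal length (", length(truth),
         " vs ", length(calls), ")")
  }
  truth <- as.character(truth)
  calls <- as.character(calls)
  keep <- calls != no_call
  if (!any(keep) && length(calls) > 0) {
    warning("all samples are no_call; confusion counts are empty")
  }
  t <- truth[keep]
  c <- calls[keep]
  bad <- setdiff(unique(c(t, c)), c(positive, negative))
  if (length(bad) > 0) {
    stop("unrecognized labels: ", paste(bad, collapse = ", "))
  }
  out <- confusion_counts(
    tp = sum(t == positive & c == positive),
    fp = sum(t == negative & c == positive),
    fn = sum(t == positive & c == negative),
    tn = sum(t == negative & c == negative)
  )
  attr(out, "n_no_call") <- sum(!keep)
  out
}

#' Construct confusion counts directly
#'
#' @param tp,fp,fn,tn nonnegative integer counts.
#' @return object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop("tp, fp, fn, tn must be nonnegative integers")
  }
  structure(stats::setNames(as.list(as.integer(counts)), names(counts)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, 2,
              dimnames = list(truth = c("pos", "neg"),
                              call = c("pos", "neg")))
  print(m)
  invisible(x)
}

#' Diagnostic performance metrics from a confusion table
#'
#' Computes sensitivity, specificity, positive and negative predictive
#' value, accuracy and the Youden index J = sensitivity + specificity - 1,
#' each with a binomial confidence interval (Youden's CI is omitted: it is
#' not a binomial proportion). Metrics whose denominator is zero are
#' returned as `NA` rather than 0.
#'
#' @param c `confusion_counts` object.
#' @param level confidence level for the intervals.
#' @param ci_method one of `"wilson"`, `"wald"`, `"clopper-pearson"`.
#' @return data.frame with columns metric, estimate, lower, upper,
#'   x (successes), n (denominator), ci_method, level.
#' @export
panel_metrics <- function(c, level = 0.95, ci_method = "wilson") {
  stopifnot(inherits(c, "confusion_counts"))
  num <- c(sensitivity = c$tp, specificity = c$tn, ppv = c$tp,
           npv = c$tn, accuracy = c$tp + c$tn)
  den <- c(sensitivity = c$tp + c$fn, specificity = c$tn + c$fp,
           ppv = c$tp + c$fp, npv = c$tn + c$fn,
           accuracy = c$tp + c$fp + c$fn + c$tn)
  est <- ifelse(den > 0, num / den, NA_real_)
  ci <- t(vapply(seq_along(num), function(i) {
    if (den[i] == 0) return(c(NA_real_, NA_real_))
    binom_ci(num[i], den[i], level = level, method = ci_method)
  }, numeric(2)))
  youden <- unname(est["sensitivity"] + est["specificity"] - 1)
  out <- data.frame(
    metric = c(names(num), "youden_j"),
    estimate = c(unname(est), youden),
    lower = c(ci[, 1], NA_real_),
    upper = c(ci[, 2], NA_real_),
    x = c(unname(num), NA_integer_),
    n = c(unname(den), NA_integer_),
    ci_method = c(rep(ci_method, length(num)), NA_character_),
    level = c(rep(level, length(num)), NA_real_),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Cohen's kappa with an asymptotic confidence interval
#'
#' Chance-corrected agreement between predicted and reference binary
#' classifications: kappa = (po - pe) / (1 - pe), where po is observed
#' agreement and pe the agreement expected from the row/column marginals.
#' The standard error is the Fleiss, Cohen & Everitt large-sample form, so
#' the CI is asymptotic (the interval is not clamped; with perfect
#' agreement it degenerates to [1, 1]).
#'
#' @param c `confusion_counts` object.
#' @param level confidence level.
#' @return list with `kappa`, `se`, `lower`, `upper`, `level`. `kappa` is
#'   `NA` when the marginals are degenerate (pe = 1).
#' @export
kappa_agreement <- function(c, level = 0.95) {
  stopifnot(inherits(c, "confusion_counts"))
  n <- c$tp + c$fp + c$fn + c$tn
  if (n == 0) stop("empty confusion table")
  # p[i, j]: truth i (pos/neg) x call j (pos/neg)
  p <- matrix(c(c$tp, c$fn, c$fp, c$tn), 2, 2, byrow = TRUE) / n
  rowm <- rowSums(p)
  colm <- colSums(p)
  po <- sum(diag(p))
  pe <- sum(rowm * colm)
  if (isTRUE(all.equal(pe, 1))) {
    return(list(kappa = NA_real_, se = NA_real_, lower = NA_real_,
                upper = NA_real_, level = level))
  }
  k <- (po - pe) / (1 - pe)
  # Fleiss-Cohen-Everitt asymptotic variance of kappa-hat
  a <- sum(diag(p) * (1 - (rowm + colm) * (1 - k))^2)
  off <- sum(p[1, 2] * (colm[1] + rowm[2])^2,
             p[2, 1] * (colm[2] + rowm[1])^2) * (1 - k)^2
  b <- (k - pe * (1 - k))^2
  se <- sqrt(max(a + off - b, 0) / (n * (1 - pe)^2))
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(kappa = k, se = se, lower = k - z * se, upper = k + z * se,
       level = level)
}

#' Binomial proportion confidence intervals
#'
#' Wilson score, Wald (normal approximation, clamped to \[0,1\] by default)
#' and Clopper-Pearson exact intervals for x successes in n trials. All
#' three are provided because published diagnostic studies mix them;
#' reported tables should label which was used.
#'
#' @param x number of successes, 0 <= x <= n.
#' @param n number of trials, n > 0.
#' @param level confidence level.
#' @param method `"wilson"`, `"wald"` or `"clopper-pearson"`.
#' @param clamp for Wald only: clamp bounds into \[0,1\].
#' @return numeric `c(lower, upper)`.
#' @export
binom_ci <- function(x, n, level = 0.95,
                     method = c("wilson", "wald", "clopper-pearson"),
                     clamp = TRUE) {
  method <- match.arg(method)
  if (length(x) != 1 || length(n) != 1 || is.na(x) || is.na(n) ||
      n <= 0 || x < 0 || x > n) {
    stop("require 0 <= x <= n with n > 0")
  }
  p <- x / n
  alpha <- 1 - level
  z <- stats::qnorm(1 - alpha / 2)
  out <- switch(method,
    wilson = {
      centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
      half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
      c(centre - half, centre + half)
    },
    wald = {
      half <- z * sqrt(p * (1 - p) / n)
      ci <- c(p - half, p + half)
      if (clamp) ci <- pmin(pmax(ci, 0), 1)
      ci
    },
    `clopper-pearson` = {
      lower <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
      upper <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
      c(lower, upper)
    }
  )
  unname(out)
}

#' Wilson score interval
#' @inheritParams binom_ci
#' @return numeric `c(lower, upper)`.
#' @export
ci_wilson <- function(x, n, level = 0.95) binom_ci(x, n, level, "wilson")

#' Wald interval (clamped to \[0,1\] by default)
#' @inheritParams binom_ci
#' @export
ci_wald <- function(x, n, level = 0.95, clamp = TRUE) {
  binom_ci(x, n, level, "wald", clamp = clamp)
}

#' Clopper-Pearson exact interval
#' @inheritParams binom_ci
#' @export
ci_clopper_pearson <- function(x, n, level = 0.95) {
  binom_ci(x, n, level, "clopper-pearson")
}

#' Empirical ROC curve and trapezoidal AUC
#'
#' Builds the empirical ROC over the unique score thresholds (ties grouped
#' into one step) with higher scores meaning more disease-like, and
#' integrates the area under the curve by the trapezoidal rule. The AUC so
#' computed equals the Mann-Whitney concordance probability
#' P(score_case > score_control) + 0.5 P(tie).
#'
#' @param scores numeric vector of per-sample scores.
#' @param truth binary truth labels.
#' @param positive label of the positive class.
#' @return object of class `roc_curve`: list with `points` (data.frame
#'   fpr, tpr, threshold, from (0,0) to (1,1)) and `auc`.
#' @export
roc_curve <- function(scores, truth, positive = "positive") {
  if (length(scores) != length(truth)) stop("length mismatch")
  ok <- !is.na(scores) & !is.na(truth)
  scores <- scores[ok]
  is_pos <- as.character(truth[ok]) == positive
  n_pos <- sum(is_pos)
  n_neg <- sum(!is_pos)
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be present to compute a ROC curve")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  pos <- is_pos[ord]
  # group tied scores into single thresholds
  last_of_group <- c(s[-1] != s[-length(s)], TRUE)
  tpr <- cumsum(pos)[last_of_group] / n_pos
  fpr <- cumsum(!pos)[last_of_group] / n_neg
  thr <- s[last_of_group]
  points <- data.frame(
    fpr = c(0, fpr), tpr = c(0, tpr), threshold = c(Inf, thr)
  )
  auc <- sum(diff(points$fpr) * (points$tpr[-1] + points$tpr[-nrow(points)]) / 2)
  structure(list(points = points, auc = auc, n_pos = n_pos, n_neg = n_neg),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat("Empirical ROC:", x$n_pos, "positives,", x$n_neg, "negatives, AUC =",
      format(x$auc, digits = 4), "\n")
  invisible(x)
}

#' Per-stratum diagnostic performance
#'
#' Splits a labelled cohort by a stratum variable (disease stage, age bin,
#' histology, cancer type, ...) and reports the confusion counts and
#' metrics per stratum plus the marginal table. Stratum counts always sum
#' to the overall counts; empty strata are kept as flagged rows rather
#' than dropped.
#'
#' @param truth,calls label vectors as in [confusion()].
#' @param strata vector of stratum labels, same length.
#' @param level,ci_method forwarded to [panel_metrics()].
#' @return data.frame, one row per stratum plus `"overall"`, with counts,
#'   sensitivity, specificity, ppv, npv, accuracy and CIs for
#'   sensitivity/specificity.
#' @export
stratified_report <- function(truth, calls, strata, level = 0.95,
                              ci_method = "wilson") {
  if (!(length(truth) == length(calls) && length(calls) == length(strata))) {
    stop("truth, calls and strata must have equal length")
  }
  levs <- if (is.factor(strata)) levels(strata) else unique(as.character(strata))
  strata <- as.character(strata)
  one_row <- function(label, idx) {
    if (length(idx) == 0) {
      return(data.frame(stratum = label, n = 0L, tp = 0L, fp = 0L, fn = 0L,
                        tn = 0L, sensitivity = NA_real_, sens_lower = NA_real_,
                        sens_upper = NA_real_, specificity = NA_real_,
                        spec_lower = NA_real_, spec_upper = NA_real_,
                        ppv = NA_real_, npv = NA_real_, accuracy = NA_real_,
                        empty = TRUE, stringsAsFactors = FALSE))
    }
    cc <- confusion(truth[idx], calls[idx])
    m <- panel_metrics(cc, level = level, ci_method = ci_method)
    g <- function(met, col) m[[col]][m$metric == met]
    data.frame(stratum = label, n = length(idx), tp = cc$tp, fp = cc$fp,
               fn = cc$fn, tn = cc$tn,
               sensitivity = g("sensitivity", "estimate"),
               sens_lower = g("sensitivity", "lower"),
               sens_upper = g("sensitivity", "upper"),
               specificity = g("specificity", "estimate"),
               spec_lower = g("specificity", "lower"),
               spec_upper = g("specificity", "upper"),
               ppv = g("ppv", "estimate"), npv = g("npv", "estimate"),
               accuracy = g("accuracy", "estimate"),
               empty = FALSE, stringsAsFactors = FALSE)
  }
  rows <- lapply(levs, function(l) one_row(l, which(strata == l)))
  rows <- c(rows, list(one_row("overall", seq_along(truth))))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Paired pre/post and two-group Wilcoxon comparisons
#'
#' Paired mode runs the two-sided Wilcoxon signed-rank test on post - pre
#' differences (zero differences dropped, ties mid-ranked, as in
#' `stats::wilcox.test`) and reports how many pairs decreased — the
#' treatment-monitoring question for methylation risk scores. Unpaired
#' mode routes to the rank-sum (Mann-Whitney) test for independent groups.
#'
#' @param pre,post equal-length numeric vectors (paired mode), or the two
#'   independent samples (unpaired mode).
#' @param paired logical; default TRUE.
#' @return list with `statistic`, `p_value`, `n_decreased`, `n_pairs`,
#'   `n_zero_diff`, `method`. When all paired differences are zero, the
#'   test is impossible: `p_value` is `NA` and `degenerate` is TRUE.
#' @export
paired_pre_post <- function(pre, post, paired = TRUE) {
  if (paired && length(pre) != length(post)) {
    stop("paired vectors must have equal length")
  }
  if (paired) {
    d <- post - pre
    n_zero <- sum(d == 0)
    n_dec <- sum(d < 0)
    if (all(d == 0)) {
      return(list(statistic = NA_real_, p_value = NA_real_,
                  n_decreased = 0L, n_pairs = length(d),
                  n_zero_diff = n_zero, degenerate = TRUE,
                  method = "wilcoxon signed-rank"))
    }
    wt <- suppressWarnings(
      stats::wilcox.test(post, pre, paired = TRUE, exact = FALSE)
    )
    list(statistic = unname(wt$statistic), p_value = wt$p.value,
         n_decreased = n_dec, n_pairs = length(d), n_zero_diff = n_zero,
         degenerate = FALSE, method = "wilcoxon signed-rank")
  } else {
    wt <- suppressWarnings(stats::wilcox.test(pre, post, exact = FALSE))
    list(statistic = unname(wt$statistic), p_value = wt$p.value,
         n_decreased = NA_integer_, n_pairs = NA_integer_,
         n_zero_diff = NA_integer_, degenerate = FALSE,
         method = "wilcoxon rank-sum")
  }
}

#' Round half away from zero
#'
#' Printed clinical percentages are conventionally rounded half-up
#' (85.491\% -> 85.49, 95.285\% -> 95.29); R's `round()` rounds half to
#' even, which disagrees on exact .5 boundaries.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @export
round_half_up <- function(x, digits = 2) {
  pow <- 10^digits
  sign(x) * floor(abs(x) * pow + 0.5 + sqrt(.Machine$double.eps)) / pow
}

#' Format a proportion as a printed percentage
#' @param p proportion in \[0,1\].
#' @param digits decimal places (default 2).
#' @export
as_percent <- function(p, digits = 2) round_half_up(100 * p, digits)
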