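#' Caller configuration for qMSP interpretation
#'
#' Collects every threshold the caller needs: the per-marker positivity Ct
#' cutoffs, the cycle ceiling of the run, the ACTB reference-gene QC gate
#' and the minimum plasma cfDNA concentration, plus the panel combination
#' mode. The ACTB gate (<= 34.8 cycles) and the cfDNA floor (0.9 ng/mL)
#' are the assay's validated acceptance rules; the 45-cycle ceiling is the
#' run length implied by the 45 - dCt risk score.
#'
#' @param markers character vector of marker names.
#' @param cutoffs named numeric vector of per-marker positivity cutoffs in
#'   cycles; a marker Ct at or below its cutoff is called positive
#'   (inclusive, mirroring the inclusive ACTB rule). Defaults to the cycle
#'   ceiling, i.e. any amplification is positive.
#' @param ct_ceiling maximum cycle number of the run (cycles).
#' @param actb_max maximum valid ACTB reference Ct (cycles).
#' @param cfdna_min minimum plasma cfDNA concentration (ng/mL); samples
#'   with a recorded concentration below this fail QC.
#' @param mode `"parallel"` (OR-rule across markers) or `"logistic"`.
#' @param coefficients for logistic mode: named vector with `"(Intercept)"`
#'   and one coefficient per marker feature.
#' @param delta_ct_score if TRUE (default) the risk score references ACTB
#'   (45 - (marker Ct - ACTB Ct)); if FALSE it uses the marker Ct alone
#'   (45 - marker Ct).
#' @return object of class `caller_config`.
#' @export
caller_config <- function(markers = c("Septin9", "Epo", "MT1A"),
                          cutoffs = NULL, ct_ceiling = 45,
                          actb_max = 34.8, cfdna_min = 0.9,
                          mode = c("parallel", "logistic"),
                          coefficients = NULL, delta_ct_score = TRUE) {
  mode <- match.arg(mode)
  if (is.null(cutoffs)) {
    cutoffs <- stats::setNames(rep(ct_ceiling, length(markers)), markers)
  }
  if (!setequal(names(cutoffs), markers)) {
    stop("`cutoffs` must be named by the markers: ",
         paste(markers, collapse = ", "))
  }
  cutoffs <- cutoffs[markers]
  if (any(cutoffs > ct_ceiling)) stop("cutoffs cannot exceed ct_ceiling")
  if (actb_max >= ct_ceiling) stop("actb_max must be below ct_ceiling")
  structure(list(markers = markers, cutoffs = cutoffs,
                 ct_ceiling = ct_ceiling, actb_max = actb_max,
                 cfdna_min = cfdna_min, mode = mode,
                 coefficients = coefficients,
                 delta_ct_score = delta_ct_score),
            class = "caller_config")
}

#' Sample-level quality-control gate
#'
#' A qMSP result is interpretable only if enough amplifiable cfDNA was
#' present: the ACTB reference Ct must be measured and at or below the
#' gate (<= 34.8), and, when a cfDNA concentration was recorded, it must
#' not fall below the floor (0.9 ng/mL).
#'
#' @param actb_ct reference-gene Ct in cycles, or `NA` if not measured.
#' @param cfdna_ng_ml plasma cfDNA concentration in ng/mL, or `NA`.
#' @param cfg `caller_config`.
#' @return list with `valid` (logical) and `reason` (`"ok"`,
#'   `"reference_gene"` or `"cfdna"`).
#' @export
qc_gate <- function(actb_ct, cfdna_ng_ml = NA_real_, cfg = caller_config()) {
  if (is.na(actb_ct) || actb_ct > cfg$actb_max) {
    return(list(valid = FALSE, reason = "reference_gene"))
  }
  if (!is.na(cfdna_ng_ml) && cfdna_ng_ml < cfg$cfdna_min) {
    return(list(valid = FALSE, reason = "cfdna"))
  }
  list(valid = TRUE, reason = "ok")
}

#' Call a single marker from its Ct value
#'
#' Positive iff the marker amplified (Ct present) at or below the marker's
#' cutoff. No amplification means no methylated template: negative. A well
#' that was not run at all (`NULL`) is invalid.
#'
#' @param ct marker Ct in cycles, `NA` for no amplification, or `NULL` if
#'   the assay was not run.
#' @param marker marker name (must be in the config).
#' @param cfg `caller_config`.
#' @return `"positive"`, `"negative"` or `"invalid"`.
#' @export
call_marker <- function(ct, marker, cfg = caller_config()) {
  if (!marker %in% cfg$markers) stop("unknown marker: ", marker)
  if (is.null(ct)) return("invalid")
  if (is.na(ct)) return("negative")
  if (ct <= 0 || ct > cfg$ct_ceiling) {
    stop("Ct for ", marker, " outside (0, ", cfg$ct_ceiling, "]: ", ct)
  }
  if (ct <= cfg$cutoffs[[marker]]) "positive" else "negative"
}

#' Combine marker calls by the parallel (OR) rule
#'
#' The panel is positive if any valid marker call is positive, negative if
#' all valid calls are negative, and `no_call` when no marker produced a
#' valid result. Parallel combination maximizes sensitivity at the cost of
#' specificity.
#'
#' @param calls character vector of per-marker calls
#'   (`positive`/`negative`/`invalid`).
#' @return `"positive"`, `"negative"` or `"no_call"`.
#' @export
combine_parallel <- function(calls) {
  valid <- calls[calls %in% c("positive", "negative")]
  if (length(valid) == 0) return("no_call")
  if (any(valid == "positive")) "positive" else "negative"
}

#' Logistic panel probability from marker Ct features
#'
#' Maps each marker to a numeric feature — the reference-adjusted signal
#' strength `actb_ct - marker_ct` (higher = more methylated template),
#' with an undetected marker imputed at the cycle ceiling — and applies a
#' fitted logistic model. Probability increases as any marker Ct falls.
#'
#' @param marker_cts named numeric vector of marker Cts (`NA` =
#'   undetected).
#' @param actb_ct reference Ct.
#' @param cfg `caller_config` carrying `coefficients` (named
#'   `"(Intercept)"` plus one per marker).
#' @return probability in \[0, 1\].
#' @export
combine_logistic <- function(marker_cts, actb_ct, cfg) {
  if (is.null(cfg$coefficients)) stop("logistic mode requires coefficients")
  beta <- cfg$coefficients
  feats <- qmsp_features(marker_cts, actb_ct, cfg)
  missing_coef <- setdiff(names(feats), names(beta))
  if (length(missing_coef) > 0) {
    stop("missing coefficients for: ", paste(missing_coef, collapse = ", "))
  }
  eta <- unname(beta["(Intercept)"]) + sum(beta[names(feats)] * feats)
  stats::plogis(eta)
}

#' Numeric features for model fitting and ROC from one qMSP record
#'
#' Signal strength per marker: `actb_ct - marker_ct`, with undetected
#' markers set to the ceiling Ct so their feature is the floor value.
#' Shared by the logistic combiner, the risk score and ROC analyses so
#' the undetected convention lives in exactly one place.
#'
#' @inheritParams combine_logistic
#' @return named numeric vector, one feature per marker.
#' @export
qmsp_features <- function(marker_cts, actb_ct, cfg = caller_config()) {
  ct <- stats::setNames(rep(cfg$ct_ceiling, length(cfg$markers)), cfg$markers)
  present <- intersect(names(marker_cts), cfg$markers)
  obs <- unlist(marker_cts[present])
  obs[is.na(obs)] <- cfg$ct_ceiling
  ct[present] <- obs
  actb_ct - ct
}

#' Methylation risk score (45 - dCt)
#'
#' Per-marker score 45 - (marker Ct - ACTB Ct), with undetected markers at
#' the cycle ceiling; the panel score is the maximum over markers, so it
#' tracks the strongest methylation signal. Higher score = more methylated
#' cfDNA. With `delta_ct_score = FALSE` in the config the reference is
#' dropped and the score is 45 - marker Ct.
#'
#' @inheritParams combine_logistic
#' @return list with `per_marker` (named numeric) and `panel` (max).
#' @export
risk_score <- function(marker_cts, actb_ct, cfg = caller_config()) {
  ct <- stats::setNames(rep(cfg$ct_ceiling, length(cfg$markers)), cfg$markers)
  present <- intersect(names(marker_cts), cfg$markers)
  obs <- unlist(marker_cts[present])
  obs[is.na(obs)] <- cfg$ct_ceiling
  ct[present] <- obs
  per <- if (cfg$delta_ct_score) {
    cfg$ct_ceiling - (ct - actb_ct)
  } else {
    cfg$ct_ceiling - ct
  }
  list(per_marker = per, panel = max(per))
}

#' Call a whole cohort of qMSP records
#'
#' Applies QC gating, per-marker calling, panel combination and risk
#' scoring to a cohort data.frame (schema of [read_qmsp_cohort()]).
#' QC-invalid samples get `panel_call = "no_call"` and are excluded from
#' downstream performance denominators.
#'
#' @param cohort data.frame with columns `sample_id`, `actb_ct`,
#'   `ct_<marker>` per marker, optional `cfdna_ng_ml`, and any metadata.
#' @param cfg `caller_config`.
#' @return data.frame: sample_id, qc_valid, qc_reason, `call_<marker>`,
#'   panel_call, risk_score, and `probability` in logistic mode; metadata
#'   columns `group`/`stage` are carried through when present.
#' @export
call_cohort <- function(cohort, cfg = caller_config()) {
  ct_cols <- paste0("ct_", cfg$markers)
  missing_cols <- setdiff(c("sample_id", "actb_ct", ct_cols), names(cohort))
  if (length(missing_cols) > 0) {
    stop("cohort is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  n <- nrow(cohort)
  cfdna <- if ("cfdna_ng_ml" %in% names(cohort)) cohort$cfdna_ng_ml
           else rep(NA_real_, n)
  actb <- cohort$actb_ct
  qc_ref_fail <- is.na(actb) | actb > cfg$actb_max
  qc_cf_fail <- !qc_ref_fail & !is.na(cfdna) & cfdna < cfg$cfdna_min
  qc_valid <- !qc_ref_fail & !qc_cf_fail
  qc_reason <- ifelse(qc_ref_fail, "reference_gene",
                      ifelse(qc_cf_fail, "cfdna", "ok"))
  res <- data.frame(sample_id = cohort$sample_id, qc_valid = qc_valid,
                    qc_reason = qc_reason, stringsAsFactors = FALSE)
  any_pos <- rep(FALSE, n)
  ct_num <- matrix(NA_real_, n, length(cfg$markers),
                   dimnames = list(NULL, cfg$markers))
  for (m in cfg$markers) {
    ct <- cohort[[paste0("ct_", m)]]
    if (any(!is.na(ct) & (ct <= 0 | ct > cfg$ct_ceiling))) {
      stop("Ct for ", m, " outside (0, ", cfg$ct_ceiling, "]")
    }
    pos <- !is.na(ct) & ct <= cfg$cutoffs[[m]]
    res[[paste0("call_", m)]] <-
      ifelse(qc_valid, ifelse(pos, "positive", "negative"), "invalid")
    any_pos <- any_pos | (qc_valid & pos)
    ct_num[, m] <- ifelse(is.na(ct), cfg$ct_ceiling, ct)
  }
  # risk score: max over markers of ceiling - dCt (or ceiling - Ct)
  score_mat <- if (cfg$delta_ct_score) {
    cfg$ct_ceiling - (ct_num - actb)
  } else {
    cfg$ct_ceiling - ct_num
  }
  score <- apply(score_mat, 1, max)
  prob <- rep(NA_real_, n)
  if (cfg$mode == "logistic") {
    beta <- cfg$coefficients
    if (is.null(beta)) stop("logistic mode requires coefficients")
    feats <- actb - ct_num            # signal strength per marker
    eta <- unname(beta["(Intercept)"]) +
      as.numeric(feats %*% beta[cfg$markers])
    prob <- stats::plogis(eta)
    res$panel_call <- ifelse(qc_valid,
                             ifelse(prob >= 0.5, "positive", "negative"),
                             "no_call")
  } else {
    res$panel_call <- ifelse(qc_valid,
                             ifelse(any_pos, "positive", "negative"),
                             "no_call")
  }
  res$risk_score <- ifelse(qc_valid, score, NA_real_)
  res$probability <- ifelse(qc_valid, prob, NA_real_)
  for (col in intersect(c("group", "stage"), names(cohort))) {
    res[[col]] <- cohort[[col]]
  }
  res
}

#' Fit logistic panel coefficients on a labelled cohort
#'
#' Ridge-regularized logistic fit of case/control status on the qMSP
#' signal features (regularization keeps the fit finite under perfect
#' separation). Deterministic: fixed lambda, no internal resampling.
#'
#' @param cohort cohort data.frame (QC-invalid rows are dropped).
#' @param labels logical or 0/1 vector, TRUE/1 = case, aligned to rows.
#' @param cfg `caller_config`.
#' @param lambda ridge penalty.
#' @return `caller_config` in logistic mode with fitted coefficients.
#' @export
fit_logistic_panel <- function(cohort, labels, cfg = caller_config(),
                               lambda = 0.01) {
  labels <- as.integer(labels)
  cfdna <- if ("cfdna_ng_ml" %in% names(cohort)) cohort$cfdna_ng_ml
           else rep(NA_real_, nrow(cohort))
  valid <- vapply(seq_len(nrow(cohort)), function(i) {
    qc_gate(cohort$actb_ct[i], cfdna[i], cfg)$valid
  }, TRUE)
  ct_cols <- paste0("ct_", cfg$markers)
  x <- t(vapply(which(valid), function(i) {
    qmsp_features(stats::setNames(as.numeric(cohort[i, ct_cols]),
                                  cfg$markers),
                  cohort$actb_ct[i], cfg)
  }, numeric(length(cfg$markers))))
  y <- labels[valid]
  if (length(unique(y)) < 2) stop("both classes required to fit the panel")
  fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                        lambda = lambda, standardize = TRUE)
  beta <- stats::setNames(as.numeric(stats::coef(fit)),
                          rownames(stats::coef(fit)))
  caller_config(markers = cfg$markers, cutoffs = cfg$cutoffs,
                ct_ceiling = cfg$ct_ceiling, actb_max = cfg$actb_max,
                cfdna_min = cfg$cfdna_min, mode = "logistic",
                coefficients = beta, delta_ct_score = cfg$delta_ct_score)
}

#' Calibrate per-marker Ct cutoffs to a target specificity
#'
#' For each marker, the cutoff is the largest Ct (up to the ceiling) such
#' that the marker-level specificity on the training controls stays at or
#' above the target: controls that never amplify impose no constraint, so
#' with clean controls the cutoff is the ceiling itself (any amplification
#' is positive). The achieved panel-level (OR-rule) specificity on the
#' training controls is reported alongside. Deterministic.
#'
#' @param cohort training cohort data.frame.
#' @param labels TRUE/1 = case; controls (FALSE/0) drive the calibration.
#' @param cfg base `caller_config` (ceiling and QC gates reused).
#' @param target_specificity minimum per-marker specificity on controls.
#' @return `caller_config` with calibrated cutoffs and attribute
#'   `achieved_panel_specificity`.
#' @export
calibrate_cutoffs <- function(cohort, labels, cfg = caller_config(),
                              target_specificity = 0.95) {
  labels <- as.integer(labels)
  cfdna <- if ("cfdna_ng_ml" %in% names(cohort)) cohort$cfdna_ng_ml
           else rep(NA_real_, nrow(cohort))
  valid <- vapply(seq_len(nrow(cohort)), function(i) {
    qc_gate(cohort$actb_ct[i], cfdna[i], cfg)$valid
  }, TRUE)
  ctrl <- valid & labels == 0
  if (!any(ctrl)) stop("no QC-valid controls to calibrate on")
  n_ctrl <- sum(ctrl)
  cutoffs <- vapply(cfg$markers, function(m) {
    cts <- cohort[[paste0("ct_", m)]][ctrl]
    amp <- sort(cts[!is.na(cts)])        # amplified controls, ascending Ct
    # false-positive budget: controls allowed to be called positive
    budget <- floor((1 - target_specificity) * n_ctrl)
    if (length(amp) <= budget) return(cfg$ct_ceiling)
    # cutoff must exclude amp[budget + 1] and everything above (inclusive
    # comparison): reuse the highest admissible control Ct when one
    # exists, otherwise sit a micro-cycle below the first excluded Ct
    upper <- amp[budget + 1]
    if (budget >= 1 && amp[budget] < upper) amp[budget] else upper - 1e-6
  }, numeric(1))
  out <- caller_config(markers = cfg$markers, cutoffs = cutoffs,
                       ct_ceiling = cfg$ct_ceiling, actb_max = cfg$actb_max,
                       cfdna_min = cfg$cfdna_min, mode = cfg$mode,
                       coefficients = cfg$coefficients,
                       delta_ct_score = cfg$delta_ct_score)
  calls <- call_cohort(cohort[ctrl, , drop = FALSE], out)
  attr(out, "achieved_panel_specificity") <-
    mean(calls$panel_call == "negative")
  out
}
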