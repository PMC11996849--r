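#' Specification of a synthetic marker-discovery dataset
#'
#' Parameters of the generative model that emulates the statistical shape
#' of the discovery-phase data: tumor and adjacent-normal tissue with a
#' set of planted hypermethylated regions, a low-methylation white-blood-
#' cell background, and noisy plasma with rare above-threshold events in
#' cancer-free controls.
#'
#' Beta values are drawn from Beta distributions parameterized by mean m
#' and concentration c (shape1 = m c, shape2 = (1 - m) c), so
#' `noise_conc` controls the spread around each group mean.
#'
#' @param n_regions total number of regions.
#' @param n_dmr number of planted hypermethylated regions.
#' @param n_tumor,n_adjacent,n_wbc,n_plasma_case,n_plasma_control sample
#'   counts per group.
#' @param base_beta mean background methylation level of tissue.
#' @param delta_planted tumor-minus-normal mean shift at planted regions.
#' @param wbc_beta WBC background mean at planted regions.
#' @param noise_conc Beta concentration (higher = tighter noise).
#' @param plasma_signal_rate probability a case plasma sample carries the
#'   tumor signal at a planted region.
#' @param tumor_fraction fraction of the planted shift visible in plasma
#'   (cfDNA dilution of the tumor signal).
#' @param seed integer RNG seed.
#' @return object of class `discovery_spec`.
#' @export
discovery_spec <- function(n_regions = 500, n_dmr = 10,
                           n_tumor = 30, n_adjacent = 30, n_wbc = 20,
                           n_plasma_case = 56, n_plasma_control = 107,
                           base_beta = 0.2, delta_planted = 0.4,
                           wbc_beta = 0.05, noise_conc = 30,
                           plasma_signal_rate = 0.6, tumor_fraction = 0.5,
                           seed = 1L) {
  num <- function(x, field, lo = 0, hi = Inf) {
    if (length(x) != 1 || is.na(x) || x < lo || x > hi) {
      stop("invalid `", field, "`: must be a single value in [", lo, ", ",
           hi, "]")
    }
    x
  }
  counts <- c(n_regions = n_regions, n_dmr = n_dmr, n_tumor = n_tumor,
              n_adjacent = n_adjacent, n_wbc = n_wbc,
              n_plasma_case = n_plasma_case,
              n_plasma_control = n_plasma_control)
  for (f in names(counts)) num(counts[[f]], f, lo = 0)
  if (n_dmr > n_regions) stop("invalid `n_dmr`: exceeds n_regions")
  num(base_beta, "base_beta", 0, 1)
  num(wbc_beta, "wbc_beta", 0, 1)
  if (base_beta + delta_planted > 1 || base_beta + delta_planted < 0) {
    stop("invalid `delta_planted`: base_beta + delta_planted must stay ",
         "within [0, 1]")
  }
  num(noise_conc, "noise_conc", lo = .Machine$double.eps)
  num(plasma_signal_rate, "plasma_signal_rate", 0, 1)
  num(tumor_fraction, "tumor_fraction", 0, 1)
  structure(as.list(environment())[c(names(counts), "base_beta",
                                     "delta_planted", "wbc_beta",
                                     "noise_conc", "plasma_signal_rate",
                                     "tumor_fraction", "seed")],
            class = "discovery_spec")
}

#' Generate a synthetic discovery methylation matrix
#'
#' Emits a region-by-sample `methyl_matrix` with tumor, adjacent-normal,
#' WBC and plasma (case/control) groups. Planted regions: tumor mean
#' `base_beta + delta_planted`, adjacent `base_beta`, WBC `wbc_beta`,
#' control plasma near the WBC background, and case plasma elevated (by
#' `tumor_fraction` of the planted shift) with probability
#' `plasma_signal_rate`. Background regions share the tissue mean in every
#' compartment, so they fail both the delta and the WBC-background screen
#' criteria in expectation. Reproducible under the spec seed.
#'
#' @param spec `discovery_spec`.
#' @return list: `matrix` (a `methyl_matrix`) and `planted` (region keys
#'   of the planted hypermethylated regions).
#' @export
generate_discovery_data <- function(spec = discovery_spec()) {
  stopifnot(inherits(spec, "discovery_spec"))
  set.seed(spec$seed)
  regions <- data.frame(chrom = "chr1",
                        start = (seq_len(spec$n_regions) - 1L) * 1000L,
                        end = (seq_len(spec$n_regions) - 1L) * 1000L + 200L)
  groups <- c(rep("tumor", spec$n_tumor), rep("adjacent", spec$n_adjacent),
              rep("wbc", spec$n_wbc),
              rep("plasma_case", spec$n_plasma_case),
              rep("plasma_control", spec$n_plasma_control))
  samples <- data.frame(
    sample_id = paste0(groups, "_", stats::ave(seq_along(groups), groups,
                                               FUN = seq_along)),
    group = groups, stringsAsFactors = FALSE)
  planted <- sort(sample.int(spec$n_regions, spec$n_dmr))
  is_planted <- seq_len(spec$n_regions) %in% planted
  plasma_bg <- spec$wbc_beta
  plasma_sig <- min(plasma_bg + spec$tumor_fraction * spec$delta_planted, 1)
  vals <- matrix(NA_real_, spec$n_regions, nrow(samples))
  for (j in seq_len(nrow(samples))) {
    g <- groups[j]
    mu <- rep(spec$base_beta, spec$n_regions)
    if (g == "tumor") {
      mu[is_planted] <- spec$base_beta + spec$delta_planted
    } else if (g == "wbc") {
      mu[is_planted] <- spec$wbc_beta
    } else if (g == "plasma_control") {
      mu[is_planted] <- plasma_bg
    } else if (g == "plasma_case") {
      carries <- stats::runif(sum(is_planted)) < spec$plasma_signal_rate
      mu[is_planted] <- ifelse(carries, plasma_sig, plasma_bg)
    }
    mu <- pmin(pmax(mu, 1e-6), 1 - 1e-6)
    vals[, j] <- stats::rbeta(spec$n_regions, mu * spec$noise_conc,
                              (1 - mu) * spec$noise_conc)
  }
  m <- methyl_matrix(regions, vals, samples)
  list(matrix = m, planted = region_key(regions)[is_planted])
}

#' Specification of a synthetic qMSP cohort
#'
#' Generative parameters for a clinical-style cohort: group sizes, per-
#' (group, marker) detection probabilities, the Ct distribution of a
#' detected marker (normal truncated at the run ceiling), the ACTB
#' reference distribution, and a QC failure rate. Defaults reproduce the
#' clinical validation cohort composition (641 cancer cases across stages
#' 0-IV plus unknown, 298 benign, 292 healthy, 198 other cancers of five
#' types) with per-marker detection probabilities calibrated so the
#' OR-rule panel hits the observed per-group rates.
#'
#' @param n_per_group named integer vector of group sizes. Recognized
#'   groups: `ec_stage0` ... `ec_stage4`, `ec_unknown`, `benign`,
#'   `healthy`, and `other:<type>`.
#' @param p_detect matrix of detection probabilities, rows named by group,
#'   columns by marker.
#' @param markers marker names.
#' @param ct_mu_pos,ct_sd_pos mean/sd (cycles) of a detected marker Ct.
#' @param actb_mu,actb_sd reference ACTB Ct distribution (cycles).
#' @param ct_ceiling maximum cycle number.
#' @param actb_max ACTB QC gate used when planting QC failures.
#' @param qc_fail_rate probability a sample fails QC (ACTB above gate).
#' @param seed integer RNG seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = NULL, p_detect = NULL,
                        markers = c("Septin9", "Epo", "MT1A"),
                        ct_mu_pos = 33, ct_sd_pos = 3,
                        actb_mu = 30, actb_sd = 1.5,
                        ct_ceiling = 45, actb_max = 34.8,
                        qc_fail_rate = 0, seed = 1L) {
  if (is.null(n_per_group)) n_per_group <- clinical_cohort_sizes()
  if (is.null(p_detect)) {
    p_detect <- clinical_detection_probs(markers,
                                         groups = names(n_per_group))
  }
  if (is.null(names(n_per_group)) || any(names(n_per_group) == "")) {
    stop("n_per_group must be fully named by group")
  }
  if (any(n_per_group < 0) || any(n_per_group != round(n_per_group))) {
    stop("invalid `n_per_group`: counts must be nonnegative integers")
  }
  if (!is.matrix(p_detect)) stop("p_detect must be a group x marker matrix")
  unknown <- setdiff(rownames(p_detect), names(n_per_group))
  if (length(unknown) > 0) {
    stop("unknown group label in p_detect: ", paste(unknown, collapse = ", "))
  }
  absent <- setdiff(names(n_per_group)[n_per_group > 0], rownames(p_detect))
  if (length(absent) > 0) {
    stop("p_detect missing rows for groups: ", paste(absent, collapse = ", "))
  }
  if (!setequal(colnames(p_detect), markers)) {
    stop("p_detect columns must match the markers")
  }
  if (any(p_detect < 0 | p_detect > 1)) {
    stop("invalid `p_detect`: probabilities must lie in [0, 1]")
  }
  if (ct_mu_pos >= ct_ceiling) {
    stop("invalid `ct_mu_pos`: must be below ct_ceiling")
  }
  if (qc_fail_rate < 0 || qc_fail_rate > 1) {
    stop("invalid `qc_fail_rate`: must lie in [0, 1]")
  }
  structure(list(n_per_group = n_per_group,
                 p_detect = p_detect[, markers, drop = FALSE],
                 markers = markers, ct_mu_pos = ct_mu_pos,
                 ct_sd_pos = ct_sd_pos, actb_mu = actb_mu,
                 actb_sd = actb_sd, ct_ceiling = ct_ceiling,
                 actb_max = actb_max, qc_fail_rate = qc_fail_rate,
                 seed = seed),
            class = "cohort_spec")
}

#' Clinical validation cohort composition
#'
#' Group sizes of the validation cohort: cancer cases by stage (32, 106,
#' 111, 204, 117, and 71 of unknown stage; 641 in all), 298 benign
#' esophageal disease, 292 healthy, and 198 other cancers (28 lung, 19
#' liver, 51 colorectal, 30 breast, 70 gastric).
#'
#' @return named integer vector.
#' @export
clinical_cohort_sizes <- function() {
  c(ec_stage0 = 32L, ec_stage1 = 106L, ec_stage2 = 111L, ec_stage3 = 204L,
    ec_stage4 = 117L, ec_unknown = 71L, benign = 298L, healthy = 292L,
    `other:lung` = 28L, `other:liver` = 19L, `other:colorectal` = 51L,
    `other:breast` = 30L, `other:gastric` = 70L)
}

#' Observed per-group panel positivity rates in the clinical cohort
#'
#' Per-stage panel sensitivities (18/32, 82/106, 96/111, 183/204, 110/117,
#' 59/71) and control false-positive rates (28 of 590 pooled benign +
#' healthy; other cancers at one minus their specificity).
#'
#' @return named numeric vector of panel positivity probabilities.
#' @export
clinical_panel_rates <- function() {
  fx <- build_fixtures()
  st <- fx$stage_tp
  ctrl_fp <- fx$clinical_overall$fp /
    (fx$clinical_overall$fp + fx$clinical_overall$tn)
  oc <- fx$other_cancer_tn
  grp <- c("0" = "ec_stage0", "I" = "ec_stage1", "II" = "ec_stage2",
           "III" = "ec_stage3", "IV" = "ec_stage4",
           "unknown" = "ec_unknown")
  c(stats::setNames(st$tp / st$n, grp[st$stage]),
    benign = ctrl_fp, healthy = ctrl_fp,
    stats::setNames(1 - oc$tn / oc$n, paste0("other:", oc$type)))
}

#' Per-marker detection probability achieving a target OR-rule rate
#'
#' With `n_markers` independent markers each detected with probability p,
#' the parallel (OR) panel fires with probability 1 - (1 - p)^n; inverting
#' gives p = 1 - (1 - target)^(1/n). Equal allocation across markers is
#' assumed.
#'
#' @param target desired panel positivity probability in \[0, 1\].
#' @param n_markers panel size.
#' @return per-marker probability.
#' @export
solve_marker_detection <- function(target, n_markers = 3) {
  if (any(target < 0 | target > 1)) stop("target must lie in [0, 1]")
  1 - (1 - target)^(1 / n_markers)
}

#' Calibrated group-by-marker detection probabilities
#'
#' @param markers marker names.
#' @param groups group labels (defaults to the clinical composition).
#' @param panel_rates named per-group target panel rates (defaults to the
#'   observed clinical rates).
#' @return matrix, groups x markers.
#' @export
clinical_detection_probs <- function(markers = c("Septin9", "Epo", "MT1A"),
                                     groups = names(clinical_cohort_sizes()),
                                     panel_rates = clinical_panel_rates()) {
  missing_g <- setdiff(groups, names(panel_rates))
  if (length(missing_g) > 0) {
    stop("no panel rate for groups: ", paste(missing_g, collapse = ", "))
  }
  p <- solve_marker_detection(panel_rates[groups], length(markers))
  matrix(rep(p, length(markers)), nrow = length(groups),
         dimnames = list(groups, markers))
}

rtrunc_norm_upper <- function(n, mu, sd, lower, upper) {
  # inversion sampler for a normal truncated to (lower, upper]
  plo <- stats::pnorm(lower, mu, sd)
  phi <- stats::pnorm(upper, mu, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mu, sd)
}

stage_label <- function(group) {
  map <- c(ec_stage0 = "0", ec_stage1 = "I", ec_stage2 = "II",
           ec_stage3 = "III", ec_stage4 = "IV", ec_unknown = "unknown")
  ifelse(group %in% names(map), map[group], NA_character_)
}

#' Generate a synthetic qMSP cohort
#'
#' One record per participant: per-marker Ct present with probability
#' `p_detect[group, marker]` and drawn from a normal truncated above at
#' the cycle ceiling; undetected markers carry `NA` (explicit "no
#' amplification", never an in-range Ct); ACTB Ct from its own truncated
#' normal, with a `qc_fail_rate` fraction pushed above the ACTB gate;
#' plasma cfDNA concentration from a lognormal shifted above the assay
#' floor. Reproducible under the spec seed.
#'
#' @param spec `cohort_spec`.
#' @return data.frame: sample_id, group, stage, truth (`positive` for
#'   cancer groups, `negative` otherwise), actb_ct, `ct_<marker>` per
#'   marker (NA = undetected), cfdna_ng_ml.
#' @export
generate_qmsp_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  groups <- rep(names(spec$n_per_group), spec$n_per_group)
  n <- length(groups)
  if (n == 0) {
    out <- data.frame(sample_id = character(), group = character(),
                      stage = character(), truth = character(),
                      actb_ct = numeric(), cfdna_ng_ml = numeric(),
                      stringsAsFactors = FALSE)
    for (m in spec$markers) out[[paste0("ct_", m)]] <- numeric()
    return(out)
  }
  fail <- stats::runif(n) < spec$qc_fail_rate
  actb <- rtrunc_norm_upper(n, spec$actb_mu, spec$actb_sd, 0, spec$actb_max)
  actb[fail] <- spec$actb_max + 0.1 +
    abs(stats::rnorm(sum(fail), 0, 2))
  actb <- pmin(actb, spec$ct_ceiling)
  cfdna <- 0.9 + stats::rlnorm(n, meanlog = log(4), sdlog = 0.5)
  cts <- matrix(NA_real_, n, length(spec$markers),
                dimnames = list(NULL, spec$markers))
  for (m in spec$markers) {
    p <- spec$p_detect[groups, m]
    det <- stats::runif(n) < p
    cts[det, m] <- rtrunc_norm_upper(sum(det), spec$ct_mu_pos,
                                     spec$ct_sd_pos, 0, spec$ct_ceiling)
  }
  out <- data.frame(
    sample_id = sprintf("s%04d", seq_len(n)),
    group = groups,
    stage = stage_label(groups),
    truth = ifelse(startsWith(groups, "ec_"), "positive", "negative"),
    actb_ct = actb, stringsAsFactors = FALSE)
  for (m in spec$markers) out[[paste0("ct_", m)]] <- cts[, m]
  out$cfdna_ng_ml <- cfdna
  rownames(out) <- NULL
  out
}
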