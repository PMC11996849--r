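SCHEMA_VERSION <- "mdmpanel-1"

#' Write and read a methylation matrix as TSV + BED + sample sheet
#'
#' The matrix travels as three plain-text files: a TSV with region keys
#' `"chrom:start-end"` (0-based half-open) in the first column and one
#' column per sample; a BED file of the regions; and a CSV sample sheet
#' with group labels. Writers are deterministic (fixed column order,
#' full-precision "." decimals regardless of locale).
#'
#' @param m `methyl_matrix`.
#' @param tsv,bed,samples_csv file paths.
#' @return (write) invisibly, the paths; (read) a `methyl_matrix`.
#' @export
write_methyl_matrix <- function(m, tsv, bed, samples_csv) {
  stopifnot(inherits(m, "methyl_matrix"))
  df <- data.frame(region = rownames(m$values), m$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(m$regions[, c("chrom", "start", "end")], bed,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  utils::write.csv(m$samples, samples_csv, row.names = FALSE, quote = FALSE)
  invisible(c(tsv = tsv, bed = bed, samples_csv = samples_csv))
}

#' @rdname write_methyl_matrix
#' @export
read_methyl_matrix <- function(tsv, bed, samples_csv) {
  for (f in c(tsv, bed, samples_csv)) {
    if (!file.exists(f)) stop("file not found: ", f)
  }
  regions <- utils::read.table(bed, sep = "\t", header = FALSE,
                               col.names = c("chrom", "start", "end"),
                               colClasses = c("character", "integer",
                                              "integer"))
  if (any(regions$start >= regions$end)) {
    stop("BED region with start >= end at line ",
         which(regions$start >= regions$end)[1])
  }
  samples <- utils::read.csv(samples_csv, stringsAsFactors = FALSE)
  tab <- utils::read.table(tsv, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  keys <- tab[[1]]
  if (!identical(keys, region_key(regions))) {
    stop("region keys in ", tsv, " do not match the BED regions")
  }
  vals <- as.matrix(tab[, -1, drop = FALSE])
  if (!identical(colnames(vals), samples$sample_id)) {
    stop("sample columns in ", tsv, " do not match the sample sheet")
  }
  bad <- which(!is.na(vals) & (vals < 0 | vals > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("methylation level outside [0,1] at region ", keys[bad[1, 1]],
         ", sample ", colnames(vals)[bad[1, 2]])
  }
  storage.mode(vals) <- "double"
  methyl_matrix(regions, vals, samples)
}

#' Write and read a qMSP cohort as CSV
#'
#' Schema: sample_id, group, stage, truth, actb_ct, one `ct_<marker>`
#' column per marker (empty cell = no amplification), cfdna_ng_ml. The
#' write/read round trip is the identity on records.
#'
#' @param cohort cohort data.frame ([generate_qmsp_cohort()] schema).
#' @param path CSV path.
#' @export
write_qmsp_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_qmsp_cohort
#' @export
read_qmsp_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  need <- c("sample_id", "actb_ct")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("cohort CSV missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id: ", df$sample_id[duplicated(df$sample_id)][1])
  }
  ct_cols <- grep("^ct_", names(df), value = TRUE)
  for (col in c("actb_ct", ct_cols)) {
    v <- df[[col]]
    if (any(!is.na(v) & v <= 0)) {
      stop("nonpositive Ct in column ", col, ", sample ",
           df$sample_id[which(!is.na(v) & v <= 0)[1]])
    }
  }
  if ("cfdna_ng_ml" %in% names(df) &&
      any(!is.na(df$cfdna_ng_ml) & df$cfdna_ng_ml < 0)) {
    stop("negative cfDNA concentration")
  }
  if ("stage" %in% names(df)) df$stage <- as.character(df$stage)
  df
}

#' Write panel calls and metric tables
#'
#' Calls go to CSV (stable column order), metric tables to TSV, and
#' metric lists to JSON; every file carries the schema version (as a
#' `schema_version` field in JSON, and as a header comment line in
#' CSV/TSV, which the paired readers skip).
#'
#' @param calls data.frame from [call_cohort()].
#' @param path output path.
#' @export
write_calls <- function(calls, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# schema=", SCHEMA_VERSION), con)
  utils::write.csv(calls, con, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_calls
#' @export
read_calls <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                  na.strings = c("", "NA"))
}

#' @rdname write_calls
#' @param metrics data.frame (e.g. [panel_metrics()] or
#'   [stratified_report()] output).
#' @export
write_metrics_tsv <- function(metrics, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# schema=", SCHEMA_VERSION), con)
  utils::write.table(metrics, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_calls
#' @param x list to serialize.
#' @export
write_metrics_json <- function(x, path) {
  x$schema_version <- SCHEMA_VERSION
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Serialize the fixture tables to JSON
#'
#' @param fx `fixture_set` from [build_fixtures()].
#' @param path output JSON path.
#' @export
write_fixtures <- function(fx = build_fixtures(), path) {
  as_plain <- function(x) {
    if (inherits(x, "confusion_counts")) {
      list(tp = x$tp, fp = x$fp, fn = x$fn, tn = x$tn)
    } else x
  }
  write_metrics_json(lapply(fx, as_plain), path)
}
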