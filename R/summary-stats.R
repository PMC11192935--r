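#' Per-variant GWAS summary statistics for one trait and ancestry
#'
#' A `summary_stats` object is a data frame of regional GWAS association
#' records (one row per variant) together with trait-level metadata. It is
#' the common currency passed between the simulator, harmonization,
#' instrument selection, colocalization and estimation stages.
#'
#' Required columns: `variant_id`, `chrom`, `pos` (1-based GRCh37),
#' `effect_allele`, `other_allele` (uppercase single bases), `eaf`
#' (effect-allele frequency), `beta`, `se`, `pval`, `n`, and `n_cases`
#' (`NA` for continuous traits).
#'
#' @param records data frame holding the columns listed above (`pval`, `n`,
#'   `n_cases` optional; `pval` is recomputed from `beta`/`se` when absent).
#' @param trait trait name, e.g. `"HDL-C"`.
#' @param ancestry ancestry label, e.g. `"EUR"` or `"EAS"`.
#' @param outcome_type `"continuous"` or `"binary"` (beta on the log odds
#'   ratio scale).
#'
#' @return A data frame of class `summary_stats` with attributes `trait`,
#'   `ancestry` and `outcome_type`.
#' @export
summary_stats <- function(records, trait, ancestry = "NA",
                          outcome_type = c("continuous", "binary")) {
  outcome_type <- match.arg(outcome_type)
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  required <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
                "eaf", "beta", "se")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols)) {
    stop2("summary_stats: missing required column(s): ",
          paste(missing_cols, collapse = ", "))
  }
  records$variant_id <- as.character(records$variant_id)
  records$chrom <- as.character(records$chrom)
  records$effect_allele <- toupper(as.character(records$effect_allele))
  records$other_allele <- toupper(as.character(records$other_allele))
  if (anyDuplicated(records$variant_id)) {
    stop2("summary_stats: duplicated variant_id values")
  }
  if (length(unique(records$chrom)) > 1L) {
    stop2("summary_stats: a regional set must lie on a single chromosome")
  }
  if (is.null(records$pval)) {
    records$pval <- 2 * stats::pnorm(-abs(records$beta / records$se))
  }
  if (is.null(records$n)) records$n <- NA_real_
  if (is.null(records$n_cases)) records$n_cases <- NA_real_
  records <- records[, c(required, "pval", "n", "n_cases")]
  rownames(records) <- NULL
  structure(records,
            trait = trait,
            ancestry = ancestry,
            outcome_type = outcome_type,
            class = c("summary_stats", "data.frame"))
}

ss_meta <- function(x) {
  list(trait = attr(x, "trait"), ancestry = attr(x, "ancestry"),
       outcome_type = attr(x, "outcome_type"))
}

# rebuild a summary_stats from a plain data frame + metadata of a template
ss_like <- function(records, template) {
  m <- ss_meta(template)
  summary_stats(records, trait = m$trait, ancestry = m$ancestry,
                outcome_type = m$outcome_type)
}

#' @export
print.summary_stats <- function(x, ...) {
  m <- ss_meta(x)
  cat(sprintf("summary_stats: %s [%s, %s], %d variants on chr %s\n",
              m$trait, m$ancestry, m$outcome_type, nrow(x),
              if (nrow(x)) x$chrom[1] else "?"))
  print(utils::head(as.data.frame(x), 6), ...)
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Read GWAS summary statistics from a tab-delimited file
#'
#' Reads the tab-delimited regional summary-statistics dialect written by
#' [write_summary_stats()]; foreign headers are supported through
#' `column_map`. Alleles are normalized to uppercase, rows with missing
#' `beta` or non-positive `se` are dropped (with a message giving the
#' count), and p-values are recomputed from `beta`/`se` when the file has
#' no p-value column.
#'
#' @param path file path.
#' @param trait,ancestry,outcome_type metadata for the resulting object.
#' @param column_map optional named character vector mapping canonical names
#'   (`variant_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`,
#'   `beta`, `se`, and optionally `pval`, `n`, `n_cases`) to the file's
#'   column names.
#' @return A [summary_stats] object.
#' @export
read_summary_stats <- function(path, trait, ancestry = "NA",
                               outcome_type = c("continuous", "binary"),
                               column_map = NULL) {
  outcome_type <- match.arg(outcome_type)
  if (!file.exists(path)) stop2("read_summary_stats: no such file: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  canonical <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
                 "eaf", "beta", "se", "pval", "n", "n_cases")
  if (!is.null(column_map)) {
    bad <- setdiff(names(column_map), canonical)
    if (length(bad)) {
      stop2("read_summary_stats: unknown canonical name(s) in column_map: ",
            paste(bad, collapse = ", "))
    }
    absent <- setdiff(unname(column_map), names(raw))
    if (length(absent)) {
      stop2("read_summary_stats: mapped column(s) not in file: ",
            paste(absent, collapse = ", "))
    }
    for (canon in names(column_map)) {
      names(raw)[names(raw) == column_map[[canon]]] <- canon
    }
  }
  required <- canonical[1:8]
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop2("read_summary_stats: required column(s) absent (configure ",
          "column_map?): ", paste(missing_cols, collapse = ", "))
  }
  for (col in intersect(canonical, names(raw))) {
    if (col %in% c("pos", "eaf", "beta", "se", "pval", "n", "n_cases")) {
      raw[[col]] <- suppressWarnings(as.numeric(raw[[col]]))
    }
  }
  usable <- is.finite(raw$beta) & is.finite(raw$se) & raw$se > 0
  n_drop <- sum(!usable)
  if (n_drop > 0) {
    message("read_summary_stats: dropped ", n_drop,
            " record(s) with missing beta/se or non-positive se")
  }
  raw <- raw[usable, , drop = FALSE]
  if (nrow(raw) == 0L) stop2("read_summary_stats: no usable records in ", path)
  summary_stats(raw, trait = trait, ancestry = ancestry,
                outcome_type = outcome_type)
}

#' Write summary statistics as tab-delimited text
#'
#' Columns: `variant_id`, `chrom`, `pos`, `effect_allele`, `other_allele`,
#' `eaf`, `beta`, `se`, `pval`, `n`, `n_cases` (empty for continuous
#' traits). Full double precision is retained so that a write/read
#' round-trip reproduces every numeric field exactly.
#'
#' @param x a [summary_stats] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(x, path) {
  stopifnot(inherits(x, "summary_stats"))
  df <- as.data.frame(x)
  for (col in c("eaf", "beta", "se", "pval", "n", "n_cases")) {
    df[[col]] <- ifelse(is.na(df[[col]]), "",
                        formatC(df[[col]], digits = 17, format = "g"))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
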