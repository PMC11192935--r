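#' Gene region with flank
#'
#' 1-based GRCh37 coordinates; the selection window is
#' `[start - flank, end + flank]`, inclusive on both ends.
#'
#' @param chrom chromosome label.
#' @param start,end gene bounds, `start <= end`.
#' @param flank bases added on each side (>= 0).
#' @return An object of class `gene_region`.
#' @export
gene_region <- function(chrom, start, end, flank = 50000) {
  if (start > end) stop2("gene_region: start must be <= end")
  if (flank < 0) stop2("gene_region: flank must be >= 0")
  structure(list(chrom = as.character(chrom), start = start, end = end,
                 flank = flank), class = "gene_region")
}

#' The CETP gene region (GRCh37) with a 50 kb flank
#'
#' Chr 16:56,995,762-57,017,757 plus 50 kb on each side, the canonical
#' cis window for CETP drug-target analyses.
#'
#' @param flank flank in bases.
#' @return A [gene_region].
#' @export
cetp_region <- function(flank = 50000) {
  gene_region("16", 56995762, 57017757, flank = flank)
}

#' Restrict summary statistics to a gene region
#'
#' Keeps variants with `start - flank <= pos <= end + flank` (inclusive).
#'
#' @param stats a [summary_stats] object on `region$chrom`.
#' @param region a [gene_region].
#' @return A [summary_stats] object; empty results are allowed with a
#'   warning.
#' @export
filter_region <- function(stats, region) {
  stopifnot(inherits(stats, "summary_stats"), inherits(region, "gene_region"))
  if (nrow(stats) && any(stats$chrom != region$chrom)) {
    stop2("filter_region: statistics are not on chromosome ", region$chrom)
  }
  lo <- region$start - region$flank
  hi <- region$end + region$flank
  keep <- stats$pos >= lo & stats$pos <= hi
  if (!any(keep)) warning("filter_region: no variants inside the window")
  ss_like(as.data.frame(stats)[keep, , drop = FALSE], stats)
}

#' Filter variants on minor-allele frequency and instrument strength
#'
#' MAF is `min(eaf, 1 - eaf)`; the per-variant F statistic is the marginal
#' Wald form `(beta / se)^2`. Variants with `MAF >= maf_min` and
#' `F >= f_min` are kept.
#'
#' @param stats a [summary_stats] object with `eaf` present for all rows.
#' @param maf_min minimum MAF (default 0.01).
#' @param f_min minimum F statistic (default 15).
#' @return A filtered [summary_stats] object.
#' @export
filter_maf_f <- function(stats, maf_min = 0.01, f_min = 15) {
  stopifnot(inherits(stats, "summary_stats"))
  if (any(!is.finite(stats$eaf))) {
    stop2("filter_maf_f: missing eaf for variant(s): ",
          paste(stats$variant_id[!is.finite(stats$eaf)], collapse = ", "))
  }
  maf <- pmin(stats$eaf, 1 - stats$eaf)
  f <- (stats$beta / stats$se)^2
  keep <- maf >= maf_min & f >= f_min
  ss_like(as.data.frame(stats)[keep, , drop = FALSE], stats)
}

#' Greedy LD clumping
#'
#' Repeatedly selects the remaining variant with the smallest p-value
#' (ties broken by smaller position, then lexicographic id), retains it,
#' and discards every remaining variant with squared correlation
#' at or above `r2_max` against it. The output preserves input order, and
#' all retained pairs have squared correlation below `r2_max`.
#'
#' @param stats a [summary_stats] object aligned to `ld` (same ids, same
#'   order).
#' @param ld an [ld_matrix].
#' @param r2_max clumping threshold on r-squared (default 0.3).
#' @return A clumped [summary_stats] object.
#' @export
ld_clump <- function(stats, ld, r2_max = 0.3) {
  stopifnot(inherits(stats, "summary_stats"), inherits(ld, "ld_matrix"))
  if (!identical(stats$variant_id, ld_ids(ld))) {
    stop2("ld_clump: statistics must be aligned to the LD matrix ",
          "(see align_to_ld)")
  }
  m <- nrow(stats)
  if (m == 0L) return(stats)
  r2 <- ld_r(ld)^2
  ord <- order(stats$pval, stats$pos, stats$variant_id)
  active <- rep(TRUE, m)
  keep <- logical(m)
  for (i in ord) {
    if (!active[i]) next
    keep[i] <- TRUE
    active[r2[i, ] >= r2_max] <- FALSE
    active[i] <- FALSE
  }
  ss_like(as.data.frame(stats)[keep, , drop = FALSE], stats)
}

#' Select cis instruments for a drug-target MR analysis
#'
#' Composes the full instrument-selection chain: harmonize exposure and
#' outcome, align both to the LD matrix, restrict to the gene region with
#' flank, apply MAF and F-statistic thresholds (computed on the exposure),
#' and greedily clump on the exposure p-value. A filter log records the
#' variants removed at each stage; its removals reconcile exactly with the
#' input/output counts.
#'
#' @param exposure,outcome [summary_stats] objects.
#' @param ld an [ld_matrix] for this ancestry.
#' @param region a [gene_region].
#' @param maf_min,f_min,r2_max filter thresholds (defaults 0.01, 15, 0.3).
#' @param palindromic_policy,eaf_tol passed to [harmonize()].
#' @return A list with the [instrument_set] (`hset`), the filter `log`
#'   (class `instrument_filter_log`), and `egger_eligible` (>= 3 surviving
#'   variants). Fewer than 2 survivors is an error naming the binding
#'   stage.
#' @export
select_instruments <- function(exposure, outcome, ld, region,
                               maf_min = 0.01, f_min = 15, r2_max = 0.3,
                               palindromic_policy = "drop", eaf_tol = 0.08) {
  h <- harmonize(exposure, outcome, palindromic_policy = palindromic_policy,
                 eaf_tol = eaf_tol)
  n_in <- length(unique(c(exposure$variant_id, outcome$variant_id)))
  log <- list(n_input_union = n_in,
              harmonize = setdiff(h$report$variant_id,
                                  h$exposure$variant_id),
              not_shared = setdiff(union(exposure$variant_id,
                                         outcome$variant_id),
                                   h$report$variant_id))

  aligned <- align_to_ld(h$exposure, ld)
  expo <- aligned$stats
  ld_a <- aligned$ld
  log$no_ld <- setdiff(h$exposure$variant_id, expo$variant_id)

  stage_check <- function(x, stage) {
    if (nrow(x) < 2L) {
      stop2("select_instruments: fewer than 2 variants remain after the '",
            stage, "' stage")
    }
    x
  }
  stage_check(expo, "ld-alignment")

  reg <- suppressWarnings(filter_region(expo, region))
  log$region <- setdiff(expo$variant_id, reg$variant_id)
  stage_check(reg, "region")

  mf <- filter_maf_f(reg, maf_min = maf_min, f_min = f_min)
  log$maf_f <- setdiff(reg$variant_id, mf$variant_id)
  stage_check(mf, "maf/F")

  ld_mf <- ld_subset(ld_a, mf$variant_id)
  cl <- ld_clump(mf, ld_mf, r2_max = r2_max)
  log$clump <- setdiff(mf$variant_id, cl$variant_id)
  stage_check(cl, "ld-clump")

  ids <- cl$variant_id
  out_df <- as.data.frame(h$outcome)
  out_df <- out_df[match(ids, out_df$variant_id), ]
  hset <- instrument_set(
    variant_ids = ids,
    b_exposure = cl$beta, se_exposure = cl$se,
    b_outcome = out_df$beta, se_outcome = out_df$se,
    eaf = cl$eaf, ld = ld_subset(ld_a, ids),
    exposure_trait = attr(exposure, "trait"),
    outcome_trait = attr(outcome, "trait"),
    ancestry = attr(outcome, "ancestry"),
    outcome_type = attr(outcome, "outcome_type"))
  log$n_output <- length(ids)
  class(log) <- "instrument_filter_log"
  list(hset = hset, log = log, egger_eligible = length(ids) >= 3L)
}

#' @export
print.instrument_filter_log <- function(x, ...) {
  cat("instrument filter log\n")
  cat(sprintf("  input union: %d\n", x$n_input_union))
  for (stage in c("not_shared", "harmonize", "no_ld", "region", "maf_f",
                  "clump")) {
    cat(sprintf("  removed at %-10s: %d\n", stage, length(x[[stage]])))
  }
  cat(sprintf("  output: %d\n", x$n_output))
  invisible(x)
}

#' Serialize a filter log as JSON
#'
#' @param log an `instrument_filter_log`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_filter_log <- function(log, path) {
  jsonlite::write_json(unclass(log), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
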