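#' Signed linkage-disequilibrium correlation matrix
#'
#' Wraps a symmetric correlation matrix (signed r, not r-squared) aligned to
#' an ordered variant list. The sign is retained because MR-Egger
#' orientation and allele harmonization need it; squaring happens only
#' inside LD clumping.
#'
#' @param r square numeric matrix of pairwise correlations.
#' @param variant_ids character vector naming rows/columns, in order.
#' @param effect_alleles optional character vector giving the allele whose
#'   dosage the correlations refer to, used by [align_to_ld()] to flip signs
#'   when the summary statistics are coded on the opposite allele.
#' @return An object of class `ld_matrix`.
#' @export
ld_matrix <- function(r, variant_ids = rownames(r), effect_alleles = NULL) {
  r <- as.matrix(r)
  if (nrow(r) != ncol(r)) stop2("ld_matrix: matrix must be square")
  if (is.null(variant_ids)) {
    variant_ids <- sprintf("v%03d", seq_len(nrow(r)))
  }
  variant_ids <- as.character(variant_ids)
  if (length(variant_ids) != nrow(r)) {
    stop2("ld_matrix: variant_ids length must equal matrix dimension")
  }
  if (max(abs(r - t(r))) > 1e-8) stop2("ld_matrix: matrix is not symmetric")
  r <- (r + t(r)) / 2
  if (max(abs(diag(r) - 1)) > 1e-8) stop2("ld_matrix: diagonal must be 1")
  diag(r) <- 1
  if (any(r < -1 - 1e-8 | r > 1 + 1e-8)) {
    stop2("ld_matrix: entries must lie in [-1, 1]")
  }
  r <- pmin(pmax(r, -1), 1)
  dimnames(r) <- list(variant_ids, variant_ids)
  if (!is.null(effect_alleles)) {
    effect_alleles <- toupper(as.character(effect_alleles))
    if (length(effect_alleles) != nrow(r)) {
      stop2("ld_matrix: effect_alleles length mismatch")
    }
    names(effect_alleles) <- variant_ids
  }
  structure(r, effect_alleles = effect_alleles,
            class = c("ld_matrix", "matrix", "array"))
}

#' Variant ids of an LD matrix, in order
#'
#' @param ld an [ld_matrix].
#' @return Character vector of variant ids.
#' @export
ld_ids <- function(ld) rownames(ld)

# plain numeric matrix view
ld_r <- function(ld) {
  r <- unclass(ld)
  attr(r, "effect_alleles") <- NULL
  r
}

ld_subset <- function(ld, ids) {
  ea <- attr(ld, "effect_alleles")
  ld_matrix(unclass(ld)[ids, ids, drop = FALSE], variant_ids = ids,
            effect_alleles = if (!is.null(ea)) ea[ids] else NULL)
}

#' Simulate an autoregressive LD correlation matrix
#'
#' First-order autoregressive structure: entry (i, j) equals
#' `decay^|i - j|`, a standard stand-in for the monotone decay of linkage
#' disequilibrium with physical distance. The result is symmetric positive
#' definite with unit diagonal for any `decay` in `[0, 1)`.
#'
#' @param n_variants number of variants (>= 1).
#' @param decay correlation between adjacent variants, in `[0, 1)`.
#' @param variant_ids optional ids (default `v001`, `v002`, ...).
#' @return An [ld_matrix].
#' @export
simulate_ld_matrix <- function(n_variants, decay, variant_ids = NULL) {
  if (!is_count(n_variants)) stop2("simulate_ld_matrix: n_variants must be a positive integer")
  if (!is.numeric(decay) || length(decay) != 1L || decay < 0 || decay >= 1) {
    stop2("simulate_ld_matrix: decay must lie in [0, 1)")
  }
  idx <- seq_len(n_variants)
  r <- decay ^ abs(outer(idx, idx, "-"))
  ld_matrix(r, variant_ids = variant_ids %||%
              sprintf("v%03d", idx))
}

#' Compute signed LD from a genotype dosage matrix
#'
#' Pairwise Pearson correlation of dosages (samples in rows, variants in
#' columns). Monomorphic columns are a hard error: their correlation is
#' undefined and downstream GLS would silently degrade.
#'
#' @param dosages numeric matrix, samples x variants.
#' @param variant_ids ids for the columns (default: column names).
#' @param effect_alleles optional alleles the dosages count.
#' @return An [ld_matrix].
#' @export
compute_ld_from_dosages <- function(dosages, variant_ids = colnames(dosages),
                                    effect_alleles = NULL) {
  dosages <- as.matrix(dosages)
  if (nrow(dosages) < 2L) stop2("compute_ld_from_dosages: need >= 2 samples")
  if (is.null(variant_ids)) {
    variant_ids <- sprintf("v%03d", seq_len(ncol(dosages)))
  }
  if (length(variant_ids) != ncol(dosages)) {
    stop2("compute_ld_from_dosages: variant_ids length mismatch")
  }
  n <- nrow(dosages)
  cm <- colMeans(dosages)
  # one BLAS pass instead of the two-pass stats::cor, which matters when
  # the panel is a full simulated cohort
  cv <- (crossprod(dosages) - n * tcrossprod(cm)) / (n - 1)
  v <- diag(cv)
  mono <- v <= 0
  if (any(mono)) {
    stop2("compute_ld_from_dosages: monomorphic column(s): ",
          paste(variant_ids[mono], collapse = ", "))
  }
  r <- cv / tcrossprod(sqrt(v))
  ld_matrix(r, variant_ids = variant_ids, effect_alleles = effect_alleles)
}

#' Align summary statistics and an LD matrix to a common variant list
#'
#' Both objects are subset and reordered to the intersection of their
#' variant ids, in the order of the summary statistics. When the LD matrix
#' carries reference effect alleles and a variant's reference allele equals
#' the statistics' other allele, that variant's row and column of r are
#' negated so the correlations refer to the statistics' effect-allele
#' dosage; variants whose reference allele matches neither allele are
#' dropped.
#'
#' @param stats a [summary_stats] object.
#' @param ld an [ld_matrix].
#' @return A list with elements `stats` and `ld`.
#' @export
align_to_ld <- function(stats, ld) {
  stopifnot(inherits(stats, "summary_stats"), inherits(ld, "ld_matrix"))
  common <- intersect(stats$variant_id, ld_ids(ld))
  if (length(common) == 0L) {
    stop2("align_to_ld: no shared variants between statistics and LD matrix")
  }
  keep <- stats$variant_id[stats$variant_id %in% common]
  r <- unclass(ld)[keep, keep, drop = FALSE]
  ea_ref <- attr(ld, "effect_alleles")
  if (!is.null(ea_ref)) {
    ea_ref <- ea_ref[keep]
    srec <- as.data.frame(stats)
    srec <- srec[match(keep, srec$variant_id), ]
    flip <- ea_ref == srec$other_allele
    unmatched <- !flip & ea_ref != srec$effect_allele
    if (any(unmatched)) {
      warning("align_to_ld: dropped ", sum(unmatched),
              " variant(s) whose LD reference allele matches neither ",
              "summary-statistic allele")
      keep <- keep[!unmatched]
      if (length(keep) == 0L) stop2("align_to_ld: no reconcilable variants")
      r <- r[keep, keep, drop = FALSE]
      ea_ref <- ea_ref[keep]
      flip <- flip[!unmatched]
    }
    if (any(flip)) {
      s <- ifelse(flip, -1, 1)
      r <- r * outer(s, s)
      ea_ref[flip] <- srec$effect_allele[match(keep[flip], srec$variant_id)]
    }
  }
  out_stats <- as.data.frame(stats)
  out_stats <- out_stats[match(keep, out_stats$variant_id), ]
  list(stats = ss_like(out_stats, stats),
       ld = ld_matrix(r, variant_ids = keep, effect_alleles = ea_ref))
}

#' Write / read an LD matrix as tab-delimited text
#'
#' Square matrix with a leading `variant_id` column and variant ids as the
#' remaining column headers.
#'
#' @param ld an [ld_matrix].
#' @param path file path.
#' @return `path` (write) or an [ld_matrix] (read).
#' @export
write_ld_matrix <- function(ld, path) {
  stopifnot(inherits(ld, "ld_matrix"))
  ids <- ld_ids(ld)
  df <- data.frame(variant_id = ids,
                   apply(unclass(ld), 2L, formatC, digits = 17, format = "g"),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("variant_id", ids)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ld_matrix
#' @export
read_ld_matrix <- function(path) {
  if (!file.exists(path)) stop2("read_ld_matrix: no such file: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  ids <- as.character(df[[1L]])
  r <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(r) <- "double"
  ld_matrix(r, variant_ids = ids)
}
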