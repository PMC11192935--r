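#' Harmonize exposure and outcome summary statistics
#'
#' Restricts both sets to their shared variants and puts the outcome on the
#' exposure's effect-allele orientation. Where the outcome's effect/other
#' alleles are swapped relative to the exposure, the outcome beta is negated
#' and its effect-allele frequency replaced by `1 - eaf`. Variants whose
#' allele pairs cannot be reconciled are dropped and reported.
#'
#' Strand-ambiguous (palindromic, A/T or C/G) variants cannot be oriented
#' from the alleles alone. Under the default `"drop"` policy they are
#' removed whenever either trait's effect-allele frequency is within
#' `eaf_tol` of 0.5 and otherwise resolved by frequency (orientations agree
#' when both frequencies fall on the same side of 0.5). `"frequency"`
#' always resolves by frequency; `"keep"` trusts the literal allele match.
#'
#' Harmonization is involutive: applying it to an already-harmonized pair
#' changes nothing.
#'
#' @param exposure,outcome [summary_stats] objects keyed by `variant_id`.
#' @param palindromic_policy `"drop"`, `"frequency"` or `"keep"`.
#' @param eaf_tol ambiguity band around 0.5 for the `"drop"` policy.
#' @return A list with the harmonized `exposure` and `outcome` and a
#'   `report` data frame (one row per input shared variant: action taken).
#' @export
harmonize <- function(exposure, outcome,
                      palindromic_policy = c("drop", "frequency", "keep"),
                      eaf_tol = 0.08) {
  stopifnot(inherits(exposure, "summary_stats"),
            inherits(outcome, "summary_stats"))
  palindromic_policy <- match.arg(palindromic_policy)
  common <- intersect(exposure$variant_id, outcome$variant_id)
  if (length(common) == 0L) {
    stop2("harmonize: no shared variants between '", attr(exposure, "trait"),
          "' and '", attr(outcome, "trait"), "'")
  }
  exp_df <- as.data.frame(exposure)
  out_df <- as.data.frame(outcome)
  exp_df <- exp_df[match(common, exp_df$variant_id), ]
  out_df <- out_df[match(common, out_df$variant_id), ]

  pal <- function(a, b) (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "C" & b == "G") | (a == "G" & b == "C")
  is_pal <- pal(exp_df$effect_allele, exp_df$other_allele)
  same <- out_df$effect_allele == exp_df$effect_allele &
    out_df$other_allele == exp_df$other_allele
  swapped <- out_df$effect_allele == exp_df$other_allele &
    out_df$other_allele == exp_df$effect_allele
  # palindromic variants share an allele set with their own swap, so the
  # literal match is uninformative there unless policy is "keep"
  action <- rep("drop_irreconcilable", length(common))
  action[same] <- "keep"
  action[swapped] <- "flip"
  if (palindromic_policy != "keep") {
    pal_idx <- which(is_pal & (same | swapped))
    if (length(pal_idx)) {
      ambiguous <- abs(exp_df$eaf[pal_idx] - 0.5) < eaf_tol |
        abs(out_df$eaf[pal_idx] - 0.5) < eaf_tol
      same_side <- (exp_df$eaf[pal_idx] - 0.5) *
        (out_df$eaf[pal_idx] - 0.5) >= 0
      act <- ifelse(same_side, "keep", "flip")
      if (palindromic_policy == "drop") {
        act[ambiguous] <- "drop_palindromic"
      }
      action[pal_idx] <- act
    }
  }

  flip <- action == "flip"
  out_df$beta[flip] <- -out_df$beta[flip]
  out_df$eaf[flip] <- 1 - out_df$eaf[flip]
  out_df$effect_allele[flip] <- exp_df$effect_allele[flip]
  out_df$other_allele[flip] <- exp_df$other_allele[flip]

  report <- data.frame(variant_id = common, action = action,
                       stringsAsFactors = FALSE)
  keep_rows <- action %in% c("keep", "flip")
  if (!any(keep_rows)) {
    stop2("harmonize: all shared variants dropped during harmonization")
  }
  list(exposure = ss_like(exp_df[keep_rows, ], exposure),
       outcome = ss_like(out_df[keep_rows, ], outcome),
       report = report)
}

#' Exposure/outcome betas on a common orientation with matched LD
#'
#' Container for the paired per-variant exposure and outcome effects
#' entering the GLS estimators, together with the LD matrix aligned to the
#' same variant order.
#'
#' @param variant_ids ordered variant ids.
#' @param b_exposure,se_exposure exposure betas and standard errors.
#' @param b_outcome,se_outcome outcome betas and standard errors.
#' @param eaf effect-allele frequencies (exposure scale).
#' @param ld an [ld_matrix] over `variant_ids` in the same order.
#' @param exposure_trait,outcome_trait,ancestry labels.
#' @param outcome_type `"continuous"` or `"binary"`.
#' @return An object of class `instrument_set`.
#' @export
instrument_set <- function(variant_ids, b_exposure, se_exposure,
                           b_outcome, se_outcome, eaf, ld,
                           exposure_trait = "exposure",
                           outcome_trait = "outcome",
                           ancestry = "NA",
                           outcome_type = c("continuous", "binary")) {
  outcome_type <- match.arg(outcome_type)
  stopifnot(inherits(ld, "ld_matrix"))
  n <- length(variant_ids)
  lens <- c(length(b_exposure), length(se_exposure), length(b_outcome),
            length(se_outcome), length(eaf), nrow(ld))
  if (any(lens != n)) stop2("instrument_set: component length mismatch")
  if (!identical(as.character(variant_ids), ld_ids(ld))) {
    stop2("instrument_set: ld variant order must match variant_ids")
  }
  if (any(!is.finite(se_exposure)) || any(se_exposure <= 0) ||
      any(!is.finite(se_outcome)) || any(se_outcome <= 0)) {
    stop2("instrument_set: standard errors must be finite and positive")
  }
  structure(list(variant_ids = as.character(variant_ids),
                 b_exposure = as.numeric(b_exposure),
                 se_exposure = as.numeric(se_exposure),
                 b_outcome = as.numeric(b_outcome),
                 se_outcome = as.numeric(se_outcome),
                 eaf = as.numeric(eaf),
                 ld = ld,
                 exposure_trait = exposure_trait,
                 outcome_trait = outcome_trait,
                 ancestry = ancestry,
                 outcome_type = outcome_type),
            class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("instrument_set: %s -> %s [%s, %s], %d variants\n",
              x$exposure_trait, x$outcome_trait, x$ancestry, x$outcome_type,
              length(x$variant_ids)))
  invisible(x)
}

# subset an instrument_set by a logical or id vector, keeping order
subset_instrument_set <- function(hset, keep) {
  ids <- if (is.logical(keep)) hset$variant_ids[keep] else as.character(keep)
  idx <- match(ids, hset$variant_ids)
  instrument_set(variant_ids = ids,
                 b_exposure = hset$b_exposure[idx],
                 se_exposure = hset$se_exposure[idx],
                 b_outcome = hset$b_outcome[idx],
                 se_outcome = hset$se_outcome[idx],
                 eaf = hset$eaf[idx],
                 ld = ld_subset(hset$ld, ids),
                 exposure_trait = hset$exposure_trait,
                 outcome_trait = hset$outcome_trait,
                 ancestry = hset$ancestry,
                 outcome_type = hset$outcome_type)
}
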