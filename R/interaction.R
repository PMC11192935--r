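#' Multiplicity plan for the interaction analysis
#'
#' Bonferroni-corrected interaction alpha (`nominal_alpha / n_traits`),
#' the replication alpha for effects required to be significant in both
#' ancestry groups (`nominal_alpha^2`), and the implied expected number of
#' false replications (`n_traits * nominal_alpha^2`).
#'
#' @param n_traits number of evaluated traits (default 32).
#' @param nominal_alpha per-test alpha (default 0.05).
#' @return A list of class `multiplicity_plan`.
#' @export
build_multiplicity_plan <- function(n_traits = 32, nominal_alpha = 0.05) {
  if (!is_count(n_traits)) stop2("build_multiplicity_plan: n_traits must be a positive integer")
  if (nominal_alpha <= 0 || nominal_alpha >= 1) {
    stop2("build_multiplicity_plan: nominal_alpha must lie in (0, 1)")
  }
  structure(list(n_traits = n_traits,
                 nominal_alpha = nominal_alpha,
                 corrected_alpha = nominal_alpha / n_traits,
                 replication_alpha = nominal_alpha^2,
                 expected_false_replications = n_traits * nominal_alpha^2),
            class = "multiplicity_plan")
}

#' Classify the cross-ancestry direction pattern
#'
#' `"discordant"` when both ancestry-specific effects are individually
#' significant at the per-ancestry alpha and their signs differ;
#' `"concordant"` when both are significant with matching sign (a
#' replicated effect at the combined alpha-squared level);
#' `"indeterminate"` otherwise.
#'
#' @param result_j,result_k `mr_result` objects for the two groups.
#' @param alpha per-ancestry significance level (default 0.05).
#' @return `"concordant"`, `"discordant"` or `"indeterminate"`.
#' @export
classify_direction <- function(result_j, result_k, alpha = 0.05) {
  fj <- result_j$chosen
  fk <- result_k$chosen
  both_sig <- fj$pval < alpha && fk$pval < alpha
  if (!both_sig) return("indeterminate")
  if (sign(fj$slope) == sign(fk$slope)) "concordant" else "discordant"
}

#' Interaction test between two ancestry-specific MR effects
#'
#' The interaction effect is the difference between the ancestry-specific
#' (Rucker-chosen) MR estimates, with standard error equal to the square
#' root of the sum of their variances; `z = delta / se_delta` is referred
#' to a standard normal, two-sided. For binary outcomes the difference is
#' taken on the log odds ratio scale, so `exp(delta)` is the ratio of the
#' two odds ratios.
#'
#' @param result_j,result_k `mr_result` objects for the same trait and
#'   outcome type in two groups.
#' @param plan a [build_multiplicity_plan()] result used for the
#'   corrected-alpha flag.
#' @param alpha per-ancestry alpha for direction classification.
#' @return A list of class `interaction_result`.
#' @export
interaction_test <- function(result_j, result_k,
                             plan = build_multiplicity_plan(),
                             alpha = 0.05) {
  stopifnot(inherits(result_j, "mr_result"), inherits(result_k, "mr_result"))
  if (!identical(result_j$outcome_trait, result_k$outcome_trait) ||
      !identical(result_j$outcome_type, result_k$outcome_type)) {
    stop2("interaction_test: results are for different traits or outcome ",
          "types")
  }
  if (!identical(result_j$chosen$estimator, result_k$chosen$estimator)) {
    message("interaction_test: Rucker-chosen models differ between ",
            "ancestries (", result_j$chosen$estimator, " vs ",
            result_k$chosen$estimator, "); proceeding on the chosen fits")
  }
  fj <- result_j$chosen
  fk <- result_k$chosen
  delta <- fj$slope - fk$slope
  se_delta <- sqrt(fj$slope_se^2 + fk$slope_se^2)
  z <- delta / se_delta
  pval <- 2 * stats::pnorm(-abs(z))
  structure(list(trait = result_j$outcome_trait,
                 outcome_type = result_j$outcome_type,
                 effect_j = fj$slope, se_j = fj$slope_se,
                 effect_k = fk$slope, se_k = fk$slope_se,
                 delta = delta, se_delta = se_delta, z = z, pval = pval,
                 or_ratio = if (identical(result_j$outcome_type, "binary"))
                   exp(delta) else NA_real_,
                 significant_at_corrected_alpha =
                   pval < plan$corrected_alpha,
                 direction_class = classify_direction(result_j, result_k,
                                                      alpha = alpha),
                 ancestry_j = result_j$ancestry,
                 ancestry_k = result_k$ancestry),
            class = "interaction_result")
}

#' @export
print.interaction_result <- function(x, ...) {
  cat(sprintf("interaction_result: %s (%s vs %s)\n", x$trait,
              x$ancestry_j %||% "j", x$ancestry_k %||% "k"))
  cat(sprintf("  delta %.4f (SE %.4f), z = %.3f, p = %.3g%s\n",
              x$delta, x$se_delta, x$z, x$pval,
              if (isTRUE(x$significant_at_corrected_alpha))
                " [< corrected alpha]" else ""))
  if (identical(x$outcome_type, "binary")) {
    cat(sprintf("  OR ratio %.3f\n", x$or_ratio))
  }
  cat(sprintf("  direction: %s\n", x$direction_class))
  invisible(x)
}

#' Flatten interaction results into a per-trait table
#'
#' @param results list of `interaction_result` objects.
#' @return A data frame (one row per trait).
#' @export
interaction_results_table <- function(results) {
  rows <- lapply(results, function(x) {
    data.frame(trait = x$trait, outcome_type = x$outcome_type,
               effect_j = x$effect_j, se_j = x$se_j,
               effect_k = x$effect_k, se_k = x$se_k,
               delta = x$delta, se_delta = x$se_delta,
               or_ratio = x$or_ratio,
               z = x$z, pval = x$pval,
               significant_at_corrected_alpha =
                 x$significant_at_corrected_alpha,
               direction_class = x$direction_class,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Calibration experiment for the interaction test
#'
#' Simulates paired two-ancestry studies under the structural model, runs
#' the full instrument-selection + MR + interaction pipeline on each
#' replicate, and reports the fraction of interaction p-values below
#' `alpha` together with the directional-discordance rate. With equal
#' protein-to-biomarker effects (`mu_j = mu_k`), equal total protein
#' effects and a fixed estimator, the rejection rate sits near `alpha`;
#' the production Rucker mode adds a few points of inflation from
#' post-model-selection mixing (see `estimator`). When `mu_j != mu_k`
#' while the total protein effects agree, the biomarker-weighted
#' estimates differ by construction and the rejection rate inflates
#' regardless of the estimator.
#'
#' @param truth_j,truth_k [truth_params] for the two groups.
#' @param reps number of simulation replicates.
#' @param seed integer seed.
#' @param n_exposure,n_outcome per-group GWAS sample sizes.
#' @param alpha nominal interaction alpha (default 0.05).
#' @param region selection window (default spans the whole simulated
#'   locus).
#' @param f_min instrument-strength threshold (default 15).
#' @param estimator `"rucker"` (the production default) or `"ivw"` /
#'   `"egger"` to hold the model fixed. Feeding model-selected estimates
#'   into the interaction test inflates its type-I error (the
#'   spuriously-selected model's standard error understates its
#'   conditional sampling spread); the fixed-IVW mode shows the test
#'   itself is calibrated.
#' @return A list of class `calibration_report`: `rejection_rate`,
#'   `discordance_rate`, `mean_delta`, `n_effective` (replicates that
#'   yielded a valid test), `reps`, `alpha`.
#' @export
interaction_calibration_experiment <- function(truth_j, truth_k, reps, seed,
                                               n_exposure = 10000,
                                               n_outcome = 10000,
                                               alpha = 0.05,
                                               region = cetp_region(),
                                               f_min = 15,
                                               estimator = "rucker") {
  if (reps < 1) stop2("interaction_calibration_experiment: reps must be >= 1")
  pvals <- rep(NA_real_, reps)
  deltas <- rep(NA_real_, reps)
  discordant <- rep(NA, reps)
  for (r in seq_len(reps)) {
    rep_seed <- child_seed(seed, 1000 + 7 * r)
    studies <- two_ancestry_scenario(truth_j, truth_k, shared_causal = TRUE,
                                     n_exposure = n_exposure,
                                     n_outcome = n_outcome, seed = rep_seed)
    fits <- lapply(studies, function(st) {
      sel <- tryCatch(
        select_instruments(st$exposure, st$outcomes[[1L]], st$ld, region,
                           f_min = f_min),
        error = function(e) NULL)
      if (is.null(sel)) return(NULL)
      tryCatch(fit_drug_target_mr(sel$hset, estimator = estimator),
               error = function(e) NULL)
    })
    if (any(vapply(fits, is.null, logical(1)))) next
    it <- tryCatch(interaction_test(fits[[1L]], fits[[2L]], alpha = alpha),
                   error = function(e) NULL)
    if (is.null(it)) next
    pvals[r] <- it$pval
    deltas[r] <- it$delta
    discordant[r] <- it$direction_class == "discordant"
  }
  ok <- !is.na(pvals)
  structure(list(rejection_rate = mean(pvals[ok] < alpha),
                 discordance_rate = mean(discordant[ok]),
                 mean_delta = mean(deltas[ok]),
                 n_effective = sum(ok), reps = reps, alpha = alpha),
            class = "calibration_report")
}

#' @export
print.calibration_report <- function(x, ...) {
  cat(sprintf(paste0("calibration_report: %d/%d effective replicates\n",
                     "  rejection rate at alpha %.3g: %.4f\n",
                     "  directional-discordance rate: %.4f\n",
                     "  mean interaction delta: %.4f\n"),
              x$n_effective, x$reps, x$alpha, x$rejection_rate,
              x$discordance_rate, x$mean_delta))
  invisible(x)
}

#' Null calibration of the Rucker model-selection rule
#'
#' Simulates summary-level no-pleiotropy nulls with independent variants
#' (outcome betas exactly proportional to exposure betas plus Gaussian
#' noise at the stated standard errors) and reports how often the Q
#' difference between IVW and Egger exceeds the selection threshold 3.84.
#' With known variances the Q difference is the Wald chi-square(1)
#' statistic for the Egger intercept, so under the null the expected
#' exceedance rate is `P(chisq(1) > 3.84) = 5%`.
#'
#' @param reps number of replicates.
#' @param seed integer seed.
#' @param n_variants instruments per replicate (default 10).
#' @param slope true causal slope (default 0.3).
#' @param se_y outcome standard error (default 0.05).
#' @return A list with `exceed_rate`, `reps`, `threshold`.
#' @export
rucker_null_calibration <- function(reps, seed, n_variants = 10,
                                    slope = 0.3, se_y = 0.05) {
  set.seed(seed)
  threshold <- stats::qnorm(0.975)^2
  ld <- simulate_ld_matrix(n_variants, 0)
  b_x <- seq(0.1, 0.4, length.out = n_variants)
  exceed <- logical(reps)
  for (r in seq_len(reps)) {
    b_y <- slope * b_x + stats::rnorm(n_variants, sd = se_y)
    hs <- instrument_set(ld_ids(ld), b_x, rep(0.01, n_variants),
                         b_y, rep(se_y, n_variants),
                         eaf = rep(0.3, n_variants), ld = ld)
    ivw <- gls_ivw(hs)
    egger <- gls_egger(hs)
    exceed[r] <- (ivw$q_stat - egger$q_stat) > threshold
  }
  list(exceed_rate = mean(exceed), reps = reps, threshold = threshold)
}
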