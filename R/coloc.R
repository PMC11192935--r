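#' Per-variant priors for colocalization
#'
#' `p1` and `p2` are the per-variant prior probabilities that a variant is
#' causal for trait 1 only or trait 2 only; `p12` is the prior that it is
#' causal for both. Defaults follow the coloc convention (1e-4, 1e-4,
#' 1e-6).
#'
#' @param p1,p2,p12 per-variant priors.
#' @return A list of class `coloc_priors`.
#' @export
coloc_priors <- function(p1 = 1e-4, p2 = 1e-4, p12 = 1e-6) {
  if (p12 <= 0 || p12 > min(p1, p2)) {
    stop2("coloc_priors: need 0 < p12 <= min(p1, p2)")
  }
  structure(list(p1 = p1, p2 = p2, p12 = p12), class = "coloc_priors")
}

#' Wakefield log approximate Bayes factor
#'
#' For a variant with estimate `beta`, standard error `se` and prior
#' effect standard deviation `prior_sd`, the log approximate Bayes factor
#' for association versus the null is `0.5 * (log(1 - r) + r * z^2)` with
#' `z = beta / se`, `V = se^2`, `W = prior_sd^2` and shrinkage
#' `W / (V + W)` in place of r.
#' Strictly increasing in `|z|` for fixed positive `V` and `W`; zero when
#' `prior_sd = 0`.
#'
#' @param beta,se per-variant estimate and standard error (vectorized).
#' @param prior_sd prior effect standard deviation (>= 0).
#' @return Log approximate Bayes factor(s).
#' @export
wakefield_labf <- function(beta, se, prior_sd) {
  if (any(!is.finite(beta)) || any(!is.finite(se)) || !is.finite(prior_sd)) {
    stop2("wakefield_labf: non-finite inputs")
  }
  if (any(se <= 0)) stop2("wakefield_labf: se must be positive")
  if (prior_sd < 0) stop2("wakefield_labf: prior_sd must be >= 0")
  v <- se^2
  w <- prior_sd^2
  r <- w / (v + w)
  z2 <- (beta / se)^2
  0.5 * (log1p(-r) + r * z2)
}

#' Posterior probabilities for the five colocalization hypotheses
#'
#' Single-causal-variant enumeration: H0 no association, H1/H2 a causal
#' variant for one trait only, H3 distinct causal variants, H4 one shared
#' causal variant. With per-variant Bayes-factor sums
#' `S1 = sum(exp(labf1))`, `S2 = sum(exp(labf2))` and
#' `S12 = sum(exp(labf1 + labf2))`, the unnormalized hypothesis weights
#' are 1, `p1*S1`, `p2*S2`, `p1*p2*(S1*S2 - S12)` and `p12*S12`,
#' accumulated in log space so extreme z-statistics do not overflow.
#'
#' @param labf1,labf2 equal-length log-ABF vectors over identical
#'   variants.
#' @param priors a [coloc_priors] object.
#' @param variant_ids optional ids (used for the lead variant).
#' @return A list of class `coloc_result` with `pp` (named vector
#'   `pp_h0` ... `pp_h4`, summing to 1), `n_variants`, `lead_variant`
#'   (highest per-variant H4 support, `labf1 + labf2`), and `priors`.
#' @export
coloc_posteriors <- function(labf1, labf2, priors = coloc_priors(),
                             variant_ids = NULL) {
  stopifnot(inherits(priors, "coloc_priors"))
  m <- length(labf1)
  if (length(labf2) != m) stop2("coloc_posteriors: length mismatch")
  if (m == 0L) stop2("coloc_posteriors: empty input")
  ls1 <- logsumexp(labf1)
  ls2 <- logsumexp(labf2)
  ls12 <- logsumexp(labf1 + labf2)
  # log(S1*S2 - S12), guarding the m = 1 case where the difference is 0
  gap <- ls12 - ls1 - ls2
  if (gap > 1e-9) {
    warning("coloc_posteriors: negative H3 weight beyond tolerance; ",
            "clipped to zero")
  }
  lh3 <- if (gap >= 0) -Inf else ls1 + ls2 + log1p(-exp(gap))
  lw <- c(h0 = 0,
          h1 = log(priors$p1) + ls1,
          h2 = log(priors$p2) + ls2,
          h3 = log(priors$p1) + log(priors$p2) + lh3,
          h4 = log(priors$p12) + ls12)
  pp <- exp(lw - logsumexp(lw))
  names(pp) <- paste0("pp_", names(lw))
  lead <- which.max(labf1 + labf2)
  structure(list(pp = pp, n_variants = m,
                 lead_variant = if (!is.null(variant_ids))
                   variant_ids[lead] else lead,
                 priors = priors),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("coloc_result over %d variants (lead: %s)\n",
              x$n_variants, x$lead_variant))
  print(round(x$pp, 4))
  invisible(x)
}

#' Cross-ancestry colocalization of one trait's regional signals
#'
#' Treats the same trait measured in two ancestry groups as the two
#' "traits" of a standard single-causal-variant colocalization: harmonizes
#' the two summary-statistic sets, restricts to the gene region (with
#' flank) and to `MAF >= maf_min`, computes Wakefield log-ABFs per group,
#' and combines them with [coloc_posteriors()]. A posterior probability of
#' a shared signal (`pp_h4`) above 0.80 is conventionally taken as
#' evidence of colocalization.
#'
#' @param stats_a,stats_b [summary_stats] for the two groups.
#' @param region a [gene_region].
#' @param priors a [coloc_priors] object.
#' @param maf_min minor-allele-frequency floor (default 0.01).
#' @param prior_sd per-trait prior effect SDs, length 2; defaults to 0.15
#'   for continuous traits (effects in SD units) and 0.2 for binary
#'   (log odds ratio scale).
#' @param palindromic_policy passed to [harmonize()].
#' @return A `coloc_result`, additionally carrying `colocalized`
#'   (`pp_h4 > 0.80`).
#' @export
cross_ancestry_coloc <- function(stats_a, stats_b, region,
                                 priors = coloc_priors(), maf_min = 0.01,
                                 prior_sd = NULL,
                                 palindromic_policy = "drop") {
  h <- harmonize(stats_a, stats_b, palindromic_policy = palindromic_policy)
  a <- suppressWarnings(filter_region(h$exposure, region))
  b <- suppressWarnings(filter_region(h$outcome, region))
  keep <- pmin(a$eaf, 1 - a$eaf) >= maf_min &
    pmin(b$eaf, 1 - b$eaf) >= maf_min
  a <- ss_like(as.data.frame(a)[keep, , drop = FALSE], a)
  b <- ss_like(as.data.frame(b)[keep, , drop = FALSE], b)
  if (nrow(a) < 2L) {
    stop2("cross_ancestry_coloc: fewer than 2 shared variants after ",
          "region/MAF filtering")
  }
  default_sd <- function(ss) {
    if (identical(attr(ss, "outcome_type"), "binary")) 0.2 else 0.15
  }
  if (is.null(prior_sd)) prior_sd <- c(default_sd(a), default_sd(b))
  prior_sd <- rep_len(prior_sd, 2L)
  labf1 <- wakefield_labf(a$beta, a$se, prior_sd[1L])
  labf2 <- wakefield_labf(b$beta, b$se, prior_sd[2L])
  res <- coloc_posteriors(labf1, labf2, priors = priors,
                          variant_ids = a$variant_id)
  res$colocalized <- unname(res$pp["pp_h4"] > 0.80)
  res$prior_sd <- prior_sd
  res
}

#' Serialize a colocalization result as JSON
#'
#' @param x a `coloc_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_coloc_json <- function(x, path) {
  out <- list(pp = as.list(x$pp), n_variants = x$n_variants,
              lead_variant = x$lead_variant,
              priors = unclass(x$priors),
              prior_sd = x$prior_sd %||% NULL,
              colocalized = x$colocalized %||% NULL)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
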