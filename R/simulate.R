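#' Structural truth parameters for the drug-target simulation
#'
#' Encodes the data-generating path model behind a drug-target MR analysis:
#' genetic variants G act on a protein P with per-variant effects `delta`;
#' P acts on a downstream biomarker X with effect `mu` (biomarker SD per
#' protein SD); X acts on the outcome D with effect `theta`; P may also act
#' on D directly, bypassing the biomarker, with effect `phi_p`; a latent
#' confounder U loads on P, X and D. The total protein effect on the
#' outcome is `omega = mu * theta + phi_p`, and a biomarker-weighted MR
#' (instrumenting through X) targets `omega / mu`, not `theta`.
#'
#' @param delta per-variant genetic effect on the protein (protein-SD per
#'   effect allele).
#' @param mu protein-to-biomarker effect.
#' @param theta biomarker-to-outcome effect.
#' @param phi_p protein-to-outcome effect bypassing the biomarker.
#' @param conf_load_p,conf_load_x,conf_load_d loadings of the standard
#'   normal confounder U on P, X and D.
#' @param outcome_type `"continuous"` or `"binary"` (logistic outcome).
#' @param prevalence target case fraction for binary outcomes, in (0, 1).
#' @return An object of class `truth_params`; `$omega` holds the implied
#'   total protein effect.
#' @export
truth_params <- function(delta, mu, theta, phi_p = 0,
                         conf_load_p = 0, conf_load_x = 0, conf_load_d = 0,
                         outcome_type = c("continuous", "binary"),
                         prevalence = 0.10) {
  outcome_type <- match.arg(outcome_type)
  delta <- as.numeric(delta)
  if (outcome_type == "binary" && (prevalence <= 0 || prevalence >= 1)) {
    stop2("truth_params: prevalence must lie in (0, 1)")
  }
  structure(list(delta = delta, mu = mu, theta = theta, phi_p = phi_p,
                 conf_load_p = conf_load_p, conf_load_x = conf_load_x,
                 conf_load_d = conf_load_d, outcome_type = outcome_type,
                 prevalence = prevalence,
                 omega = mu * theta + phi_p),
            class = "truth_params")
}

#' Default locus truth: 60 variants, 3 causal
#'
#' The stock simulated locus used throughout the package: 60 variants with
#' three causal ones (indices 10, 30, 50) of effect 0.25 protein-SD per
#' allele (a strong cis locus, as expected for a protein's own gene
#' region), `mu = 0.5`, `theta = 0.4`, no bypass pleiotropy, and moderate
#' confounding (loadings 0.3) on all three downstream nodes.
#'
#' @param n_variants locus size.
#' @param causal_idx indices of causal variants.
#' @param delta_causal effect size at causal variants.
#' @param ... overrides passed on to [truth_params()].
#' @return A [truth_params] object.
#' @export
default_truth <- function(n_variants = 60, causal_idx = c(10, 30, 50),
                          delta_causal = 0.25, ...) {
  delta <- numeric(n_variants)
  delta[causal_idx] <- delta_causal
  args <- utils::modifyList(
    list(delta = delta, mu = 0.5, theta = 0.4, phi_p = 0,
         conf_load_p = 0.3, conf_load_x = 0.3, conf_load_d = 0.3),
    list(...))
  do.call(truth_params, args)
}

# deterministic variant annotation spanning a CETP-like window on chr 16;
# alleles drawn from non-palindromic pairs so harmonization is exact
default_variants <- function(n_variants, chrom = "16",
                             start = 56945762L, end = 57067757L) {
  pos <- round(seq(start, end, length.out = n_variants))
  pairs <- rbind(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                 c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))
  idx <- ((seq_len(n_variants) - 1L) %% nrow(pairs)) + 1L
  data.frame(variant_id = sprintf("v%03d", seq_len(n_variants)),
             chrom = chrom, pos = pos,
             effect_allele = pairs[idx, 1L],
             other_allele = pairs[idx, 2L],
             stringsAsFactors = FALSE)
}

#' One ancestry's simulation scenario
#'
#' Bundles the structural truth with ancestry-specific LD, allele
#' frequencies, sample sizes and variant annotation.
#'
#' @param truth a [truth_params] object.
#' @param ld an [ld_matrix]; its dimension must equal `length(maf)` and
#'   `length(truth$delta)`.
#' @param maf per-variant minor-allele frequencies in (0, 0.5].
#' @param n_exposure,n_outcome GWAS sample sizes for the biomarker
#'   (exposure) and outcome cohorts.
#' @param label ancestry tag, e.g. `"EUR"`.
#' @param variants optional annotation data frame (`variant_id`, `chrom`,
#'   `pos`, `effect_allele`, `other_allele`); defaults to a CETP-like
#'   window on chromosome 16.
#' @return An object of class `ancestry_scenario`.
#' @export
ancestry_scenario <- function(truth, ld, maf, n_exposure, n_outcome,
                              label = "NA", variants = NULL) {
  stopifnot(inherits(truth, "truth_params"), inherits(ld, "ld_matrix"))
  maf <- as.numeric(maf)
  if (any(maf <= 0 | maf > 0.5)) {
    stop2("ancestry_scenario: maf entries must lie in (0, 0.5]")
  }
  m <- length(maf)
  if (nrow(ld) != m || length(truth$delta) != m) {
    stop2("ancestry_scenario: ld, maf and truth$delta dimensions disagree")
  }
  if (is.null(variants)) variants <- default_variants(m)
  if (nrow(variants) != m) stop2("ancestry_scenario: variants row count mismatch")
  variants$variant_id <- ld_ids(ld)
  structure(list(truth = truth, ld = ld, maf = maf,
                 n_exposure = n_exposure, n_outcome = n_outcome,
                 label = label, variants = variants),
            class = "ancestry_scenario")
}

#' Simulate individual-level data under the structural model
#'
#' Genotypes are built from a latent Gaussian with the scenario's LD
#' correlation, cut at the Hardy-Weinberg quantiles of the target MAF
#' (below `qnorm((1-maf)^2)` gives 0 copies, above `qnorm(1-maf^2)` gives
#' 2), so realized genotype correlations approximate (attenuated towards
#' zero) the latent LD. The phenotypes
#' follow the path model of [truth_params()]; noise variances for P and X
#' are solved so both are approximately unit variance, making `delta` and
#' `mu` directly interpretable in SD units. Binary outcomes are drawn from
#' a logistic model whose intercept is solved numerically for the target
#' prevalence.
#'
#' @param scenario an [ancestry_scenario].
#' @param n sample size.
#' @param seed integer seed; identical seeds give identical output.
#' @return A list with `genotypes` (n x m allele-count matrix with variant
#'   ids as column names), `P`, `X`, `D` and `U` vectors.
#' @export
simulate_individual_level <- function(scenario, n, seed) {
  stopifnot(inherits(scenario, "ancestry_scenario"))
  set.seed(seed)
  truth <- scenario$truth
  m <- length(scenario$maf)
  L <- tryCatch(chol(ld_r(scenario$ld)),
                error = function(e) stop2(
                  "simulate_individual_level: LD matrix is not positive ",
                  "definite: ", conditionMessage(e)))
  z0 <- stats::qnorm((1 - scenario$maf)^2)
  z1 <- stats::qnorm(1 - scenario$maf^2)
  cpp_seed <- as.integer(floor(stats::runif(1) * 2147483646))
  G <- latent_genotypes_cpp(n, L, z0, z1, cpp_seed)
  colnames(G) <- ld_ids(scenario$ld)

  U <- stats::rnorm(n)
  gd <- as.vector(G %*% truth$delta)
  var_eg <- 1 - stats::var(gd) - truth$conf_load_p^2
  if (var_eg < 0.05) {
    warning("simulate_individual_level: genetic + confounder variance of P ",
            "near/above 1; flooring residual variance at 0.05")
    var_eg <- 0.05
  }
  P <- gd + truth$conf_load_p * U + stats::rnorm(n, sd = sqrt(var_eg))
  cov_pu <- truth$conf_load_p  # population covariance of P and U
  var_ex <- 1 - truth$mu^2 * 1 - truth$conf_load_x^2 -
    2 * truth$mu * truth$conf_load_x * cov_pu
  if (var_ex < 0.05) {
    warning("simulate_individual_level: structural variance of X ",
            "near/above 1; flooring residual variance at 0.05")
    var_ex <- 0.05
  }
  X <- truth$mu * P + truth$conf_load_x * U + stats::rnorm(n, sd = sqrt(var_ex))

  eta <- truth$theta * X + truth$phi_p * P + truth$conf_load_d * U
  if (truth$outcome_type == "continuous") {
    D <- eta + stats::rnorm(n)
  } else {
    f <- function(c0) mean(stats::plogis(c0 + eta)) - truth$prevalence
    c0 <- stats::uniroot(f, c(-40, 40))$root
    D <- stats::rbinom(n, 1L, stats::plogis(c0 + eta))
  }
  list(genotypes = G, P = P, X = X, D = D, U = U)
}

#' Summarize a trait against genotypes into GWAS records
#'
#' Per-variant marginal association: simple linear regression of the trait
#' on allele count for continuous traits, univariate logistic regression
#' (beta = log odds ratio) for binary traits. Monomorphic variants are
#' flagged with missing beta/se and excluded by downstream readers.
#'
#' @param genotypes n x m allele-count matrix.
#' @param trait numeric trait vector of length n (0/1 for binary).
#' @param outcome_type `"continuous"` or `"binary"`.
#' @param variants annotation data frame as in [ancestry_scenario()].
#' @param trait_name,ancestry metadata labels.
#' @return A [summary_stats] object (monomorphic variants carry `NA` beta).
#' @export
summarize_to_gwas <- function(genotypes, trait,
                              outcome_type = c("continuous", "binary"),
                              variants = NULL, trait_name = "trait",
                              ancestry = "NA") {
  outcome_type <- match.arg(outcome_type)
  G <- if (is.matrix(genotypes)) genotypes else as.matrix(genotypes)
  n <- nrow(G)
  if (length(trait) != n) stop2("summarize_to_gwas: row count mismatch")
  m <- ncol(G)
  if (is.null(variants)) variants <- default_variants(m)
  if (!is.null(colnames(G))) variants$variant_id <- colnames(G)

  eaf <- colMeans(G) / 2
  mono <- eaf == 0 | eaf == 1
  beta <- se <- pval <- rep(NA_real_, m)
  if (outcome_type == "continuous") {
    y <- as.numeric(trait)
    gm <- colMeans(G)
    ym <- mean(y)
    sxx <- colSums(G^2) - n * gm^2
    sxy <- as.vector(crossprod(G, y)) - n * gm * ym
    syy <- sum(y^2) - n * ym^2
    ok <- !mono
    beta[ok] <- sxy[ok] / sxx[ok]
    sigma2 <- pmax(syy - beta[ok] * sxy[ok], 0) / (n - 2)
    se[ok] <- sqrt(sigma2 / sxx[ok])
    tt <- beta[ok] / se[ok]
    pval[ok] <- 2 * stats::pt(-abs(tt), df = n - 2)
  } else {
    y <- as.integer(trait)
    for (j in which(!mono)) {
      fit <- suppressWarnings(
        stats::glm.fit(cbind(1, G[, j]), y, family = stats::binomial()))
      cf <- fit$coefficients[2L]
      # Wald SE from the inverse Fisher information
      w <- fit$weights
      xw <- cbind(1, G[, j])
      info <- crossprod(xw * sqrt(w))
      vc <- tryCatch(solve(info), error = function(e) NULL)
      if (is.null(vc) || !is.finite(cf)) next
      beta[j] <- cf
      se[j] <- sqrt(vc[2L, 2L])
      pval[j] <- 2 * stats::pnorm(-abs(beta[j] / se[j]))
    }
  }
  rec <- variants
  rec$eaf <- eaf
  rec$beta <- beta
  rec$se <- se
  rec$pval <- pval
  rec$n <- n
  rec$n_cases <- if (outcome_type == "binary") sum(y) else NA_real_
  summary_stats(rec, trait = trait_name, ancestry = ancestry,
                outcome_type = outcome_type)
}

#' Simulate a full two-sample GWAS study for one ancestry
#'
#' Draws independent exposure and outcome cohorts under the scenario,
#' summarizes the biomarker X in the exposure cohort and the outcome D in
#' the outcome cohort, and recomputes the LD matrix from the simulated
#' exposure genotypes so the estimator inputs are self-consistent with the
#' realized (not just the target) genotype correlations. The global seed
#' fans out to per-stage child seeds by fixed offsets.
#'
#' @param scenario an [ancestry_scenario].
#' @param seed integer seed.
#' @param exposure_name,outcome_name trait labels.
#' @return A list of class `simulated_study` with `exposure` and `outcomes`
#'   (a one-element list) as [summary_stats], `ld` recomputed from the
#'   exposure genotypes, plus `truth`, `label`, `seed`.
#' @export
simulate_study <- function(scenario, seed, exposure_name = "biomarker",
                           outcome_name = "outcome") {
  stopifnot(inherits(scenario, "ancestry_scenario"))
  expo <- simulate_individual_level(scenario, scenario$n_exposure,
                                    seed = child_seed(seed, 1000))
  outc <- simulate_individual_level(scenario, scenario$n_outcome,
                                    seed = child_seed(seed, 2000))
  ss_x <- summarize_to_gwas(expo$genotypes, expo$X, "continuous",
                            variants = scenario$variants,
                            trait_name = exposure_name,
                            ancestry = scenario$label)
  ss_d <- summarize_to_gwas(outc$genotypes, outc$D,
                            scenario$truth$outcome_type,
                            variants = scenario$variants,
                            trait_name = outcome_name,
                            ancestry = scenario$label)
  poly <- colMeans(expo$genotypes) / 2
  keep <- poly > 0 & poly < 1
  ld <- compute_ld_from_dosages(expo$genotypes[, keep, drop = FALSE],
                                variant_ids = colnames(expo$genotypes)[keep],
                                effect_alleles =
                                  scenario$variants$effect_allele[keep])
  structure(list(exposure = ss_x, outcomes = list(ss_d), ld = ld,
                 truth = scenario$truth, label = scenario$label, seed = seed),
            class = "simulated_study")
}

#' Paired two-ancestry simulated studies
#'
#' Builds two ancestry scenarios sharing a variant grid but with their own
#' LD decay and allele-frequency spectra, places the causal variants either
#' at coinciding indices (`shared_causal = TRUE`, the shared-signal truth
#' behind colocalization hypothesis H4) or at disjoint indices (H3 truth;
#' a `truth_k` with all-zero `delta` gives the one-sided H1/H2 truth), and
#' simulates both studies.
#'
#' @param truth_j,truth_k [truth_params] for the two groups (same variant
#'   count).
#' @param shared_causal logical; see above.
#' @param n_exposure,n_outcome sample sizes (recycled to both groups).
#' @param decay per-group LD decay parameters.
#' @param labels ancestry tags.
#' @param seed integer seed; group-specific child seeds derive from it.
#' @return A list of two `simulated_study` objects, named by `labels`.
#' @export
two_ancestry_scenario <- function(truth_j, truth_k, shared_causal = TRUE,
                                  n_exposure = 10000, n_outcome = 10000,
                                  decay = c(0.8, 0.7),
                                  labels = c("EUR", "EAS"), seed = 1) {
  m <- length(truth_j$delta)
  if (length(truth_k$delta) != m) {
    stop2("two_ancestry_scenario: truth_j and truth_k variant counts differ")
  }
  nz_j <- which(truth_j$delta != 0)
  nz_k <- which(truth_k$delta != 0)
  if (length(nz_k)) {
    delta_k <- numeric(m)
    if (shared_causal) {
      take <- nz_j[seq_len(min(length(nz_j), length(nz_k)))]
      if (length(take) < length(nz_k)) {
        take <- c(take, setdiff(seq_len(m), take)[
          seq_len(length(nz_k) - length(take))])
      }
    } else {
      pool <- setdiff(seq_len(m), nz_j)
      if (length(pool) < length(nz_k)) {
        stop2("two_ancestry_scenario: not enough variants for disjoint ",
              "causal sets")
      }
      take <- pool[seq_len(length(nz_k))]
    }
    delta_k[take] <- truth_k$delta[nz_k]
    truth_k$delta <- delta_k
  }
  n_exposure <- rep_len(n_exposure, 2L)
  n_outcome <- rep_len(n_outcome, 2L)
  variants <- default_variants(m)
  set.seed(child_seed(seed, 10))
  maf_j <- stats::runif(m, 0.05, 0.5)
  set.seed(child_seed(seed, 20))
  maf_k <- stats::runif(m, 0.05, 0.5)
  scen_j <- ancestry_scenario(truth_j, simulate_ld_matrix(m, decay[1]),
                              maf_j, n_exposure[1], n_outcome[1],
                              label = labels[1], variants = variants)
  scen_k <- ancestry_scenario(truth_k, simulate_ld_matrix(m, decay[2]),
                              maf_k, n_exposure[2], n_outcome[2],
                              label = labels[2], variants = variants)
  out <- list(simulate_study(scen_j, seed = child_seed(seed, 100)),
              simulate_study(scen_k, seed = child_seed(seed, 200)))
  names(out) <- labels
  out
}

#' Write the truth parameters as a JSON sidecar
#'
#' @param truth a [truth_params] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "truth_params"))
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
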