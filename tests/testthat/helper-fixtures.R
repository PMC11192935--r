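# Shared fixture builders; everything is generated in code, nothing on disk.

# minimal well-formed summary_stats from vectors
make_stats <- function(beta, se, pval = NULL, eaf = NULL, pos = NULL,
                       ids = NULL, trait = "trait", ancestry = "EUR",
                       outcome_type = "continuous",
                       effect_allele = NULL, other_allele = NULL) {
  m <- length(beta)
  ids <- ids %||% sprintf("v%03d", seq_len(m))
  summary_stats(data.frame(
    variant_id = ids, chrom = "16",
    pos = pos %||% (56950000 + seq_len(m) * 1000),
    effect_allele = effect_allele %||% rep("A", m),
    other_allele = other_allele %||% rep("G", m),
    eaf = eaf %||% rep(0.3, m), beta = beta, se = se,
    pval = pval %||% (2 * stats::pnorm(-abs(beta / se))),
    n = 10000, stringsAsFactors = FALSE),
    trait = trait, ancestry = ancestry, outcome_type = outcome_type)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# harmonized instrument set straight from vectors
make_hset <- function(b_x, b_y, se_y, rho = NULL, se_x = NULL, eaf = NULL,
                      outcome_type = "continuous") {
  m <- length(b_x)
  ld <- if (is.null(rho)) simulate_ld_matrix(m, 0) else
    ld_matrix(rho, variant_ids = sprintf("v%03d", seq_len(m)))
  instrument_set(variant_ids = ld_ids(ld),
                 b_exposure = b_x, se_exposure = se_x %||% rep(0.01, m),
                 b_outcome = b_y, se_outcome = se_y,
                 eaf = eaf %||% rep(0.3, m), ld = ld,
                 outcome_type = outcome_type)
}

# random positive-definite correlation matrix of dimension m
random_corr <- function(m, seed) {
  set.seed(seed)
  a <- matrix(stats::rnorm(m * (m + 2)), m + 2, m)
  r <- stats::cov2cor(crossprod(a))
  (r + t(r)) / 2
}

# independent GLS oracle: whiten with the cholesky of Sigma, then use
# base lm.fit on the transformed system -- a different computational route
# from the package's normal-equation solve
gls_oracle <- function(Z, y, sigma) {
  ch <- chol(sigma)
  wz <- backsolve(ch, Z, transpose = TRUE)
  wy <- backsolve(ch, y, transpose = TRUE)
  fit <- stats::lm.fit(wz, wy)
  coef <- unname(fit$coefficients)
  vcov <- solve(crossprod(wz))
  resid_w <- wy - wz %*% coef
  list(coef = coef, se = sqrt(diag(vcov)), q = sum(resid_w^2))
}
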