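test_that("build_sigma scales LD by outcome SEs and ridges near-singular LD", {
  # identity LD: Sigma = diag(se^2)
  ld <- simulate_ld_matrix(2, 0)
  s <- build_sigma(c(0.1, 0.2), ld)
  expect_equal(unname(s), diag(c(0.01, 0.04)), ignore_attr = TRUE)
  # off-diagonal = se_i * r_ij * se_j
  ld2 <- ld_matrix(matrix(c(1, 0.5, 0.5, 1), 2))
  s2 <- build_sigma(c(0.1, 0.2), ld2)
  expect_equal(s2[1, 2], 0.1 * 0.5 * 0.2)
  # near-perfect correlation: ridge applied, solve succeeds
  ld3 <- ld_matrix(matrix(c(1, 0.999999995, 0.999999995, 1), 2))
  s3 <- build_sigma(c(0.1, 0.1), ld3)
  expect_true(attr(s3, "ridged"))
  expect_no_error(solve(s3))
  expect_error(build_sigma(c(0.1, NA), ld), "non-finite")
})

test_that("GLS IVW reproduces forced cases and the textbook identity-LD limit", {
  # single variant: ratio estimate, zero heterogeneity
  f1 <- gls_ivw(make_hset(0.5, 0.1, 0.05))
  expect_equal(f1$slope, 0.2)
  expect_equal(f1$q_stat, 0, tolerance = 1e-12)
  expect_equal(f1$q_df, 0L)
  # exact proportionality: slope 0.5, Q = 0 for any SEs
  f2 <- gls_ivw(make_hset(c(0.2, 0.4), c(0.1, 0.2), c(0.03, 0.07)))
  expect_equal(f2$slope, 0.5, tolerance = 1e-12)
  expect_equal(f2$q_stat, 0, tolerance = 1e-10)
  # identity LD equals the classic inverse-variance-weighted estimate
  set.seed(31)
  bx <- runif(6, 0.1, 0.5); by <- 0.3 * bx + rnorm(6, 0, 0.02)
  se <- runif(6, 0.02, 0.08)
  fit <- gls_ivw(make_hset(bx, by, se))
  w <- 1 / se^2
  expect_equal(fit$slope, sum(w * bx * by) / sum(w * bx^2),
               tolerance = 1e-12)
  expect_equal(fit$slope_se, sqrt(1 / sum(w * bx^2)), tolerance = 1e-12)
  # 95% CI uses +-1.959964 and the normal reference
  expect_equal(fit$ci_high - fit$slope, 1.959964 * fit$slope_se)
  expect_equal(fit$pval, 2 * pnorm(-abs(fit$slope / fit$slope_se)))
})

test_that("GLS IVW and Egger agree with a whitened-lm oracle under LD", {
  for (seed in 1:6) {
    set.seed(seed)
    m <- sample(3:6, 1)
    rho <- random_corr(m, seed = 300 + seed)
    bx <- runif(m, -0.4, 0.6)
    by <- 0.4 * bx + rnorm(m, 0, 0.05)
    se <- runif(m, 0.02, 0.1)
    hs <- make_hset(bx, by, se, rho = rho)
    sigma <- ld_r(hs$ld) * tcrossprod(se)

    ivw <- gls_ivw(hs)
    o_ivw <- gls_oracle(cbind(bx), by, sigma)
    expect_equal(ivw$slope, o_ivw$coef[1], tolerance = 1e-10)
    expect_equal(ivw$slope_se, o_ivw$se[1], tolerance = 1e-10)
    expect_equal(ivw$q_stat, o_ivw$q, tolerance = 1e-10)

    egger <- gls_egger(hs)
    s <- ifelse(bx < 0, -1, 1)
    sigma_f <- (rho * outer(s, s)) * tcrossprod(se)
    o_egg <- gls_oracle(cbind(1, s * bx), s * by, sigma_f)
    expect_equal(egger$intercept, o_egg$coef[1], tolerance = 1e-10)
    expect_equal(egger$slope, o_egg$coef[2], tolerance = 1e-10)
    expect_equal(egger$slope_se, o_egg$se[2], tolerance = 1e-10)
    expect_equal(egger$q_stat, o_egg$q, tolerance = 1e-10)

    # nesting: the extra Egger parameter cannot increase the residual Q
    expect_gte(ivw$q_stat - egger$q_stat, -1e-8)
    # leverage traces equal the parameter counts
    expect_equal(sum(ivw$leverage), 1, tolerance = 1e-10)
    expect_equal(sum(egger$leverage), 2, tolerance = 1e-10)
  }
})

test_that("Egger reproduces exact-line cases and is orientation invariant", {
  # collinear points with intercept 0.04, slope 0.5
  hs <- make_hset(c(0.2, 0.4, 0.6), c(0.14, 0.24, 0.34), rep(0.05, 3))
  f <- gls_egger(hs)
  expect_equal(f$slope, 0.5, tolerance = 1e-10)
  expect_equal(f$intercept, 0.04, tolerance = 1e-10)
  expect_equal(f$q_stat, 0, tolerance = 1e-10)
  expect_equal(f$q_df, 1L)
  # zero-pleiotropy line: intercept 0
  hs0 <- make_hset(c(0.2, 0.4, 0.6), c(0.1, 0.2, 0.3), rep(0.05, 3))
  f0 <- gls_egger(hs0)
  expect_equal(f0$intercept, 0, tolerance = 1e-10)
  expect_equal(f0$slope, 0.5, tolerance = 1e-10)
  # fewer than 3 variants refuse
  expect_error(gls_egger(make_hset(c(0.2, 0.4), c(0.1, 0.2), rep(0.05, 2))),
               "3 variants")
  # flipping the allele coding of one variant leaves both coefficients
  set.seed(8)
  rho <- random_corr(4, seed = 77)
  bx <- c(0.3, -0.2, 0.4, 0.25); by <- 0.5 * bx + rnorm(4, 0, 0.03)
  se <- rep(0.04, 4)
  base <- gls_egger(make_hset(bx, by, se, rho = rho))
  flip <- c(1, 1, -1, 1)
  flipped <- gls_egger(make_hset(flip * bx, flip * by, se,
                                 rho = rho * outer(flip, flip)))
  expect_equal(flipped$slope, base$slope, tolerance = 1e-10)
  expect_equal(flipped$intercept, base$intercept, tolerance = 1e-10)
})

test_that("diagnostics remove planted outliers but spare exact-fit data", {
  # exact proportionality: nothing removed
  hs <- make_hset(c(0.2, 0.3, 0.4, 0.5), 0.5 * c(0.2, 0.3, 0.4, 0.5),
                  rep(0.05, 4))
  d <- diagnostics_filter(hs)
  expect_equal(nrow(d$removed), 0L)
  expect_false(d$q_warning)
  # one variant far off an otherwise proportional set
  bx <- c(0.2, 0.3, 0.4, 0.5, 0.35)
  by <- 0.5 * bx
  by[5] <- by[5] + 0.5   # standardized residual 0.5/0.05 = 10 -> q = 100
  hs2 <- make_hset(bx, by, rep(0.05, 5))
  # independent residual oracle: whitened residual of the refit
  fit <- gls_ivw(hs2)
  expect_gt(fit$outlier_stat[5], 10.83)
  d2 <- diagnostics_filter(hs2)
  expect_identical(d2$removed$variant_id, "v005")
  expect_identical(d2$removed$reason, "outlier")
  expect_equal(length(d2$hset$variant_ids), 4L)
  # all flagged -> error
  expect_error(diagnostics_filter(make_hset(c(1, 1), c(5, -5), c(0.01, 0.01))),
               "all variants|fewer than 2")
})

test_that("Rucker selection applies the 3.84 rule and handles missing Egger", {
  mk <- function(q, est, n = 5) {
    f <- gls_ivw(make_hset(runif(n, 0.2, 0.5), runif(n, 0, 0.2),
                           rep(0.05, n)))
    f$q_stat <- q
    f$estimator <- est
    f
  }
  set.seed(2)
  ivw <- mk(10, "IVW"); egger <- mk(5, "Egger")
  egger$variant_ids <- ivw$variant_ids
  sel <- rucker_select(ivw, egger)
  expect_identical(sel$chosen$estimator, "Egger")
  expect_equal(sel$model_rule, 5)
  ivw2 <- mk(5, "IVW"); egger2 <- mk(4, "Egger")
  egger2$variant_ids <- ivw2$variant_ids
  sel2 <- rucker_select(ivw2, egger2)
  expect_identical(sel2$chosen$estimator, "IVW")
  # Egger unavailable: IVW chosen with flag
  sel3 <- rucker_select(ivw, NULL)
  expect_identical(sel3$chosen$estimator, "IVW")
  expect_true(sel3$egger_unavailable)
})

test_that("binary outcomes are reported as odds ratios", {
  set.seed(4)
  bx <- runif(4, 0.3, 0.5)
  by <- -0.117 * bx
  hs <- make_hset(bx, by, rep(0.05, 4), outcome_type = "binary")
  res <- fit_drug_target_mr(hs)
  expect_identical(res$effect_scale, "odds-ratio")
  expect_equal(res$chosen$slope, -0.117, tolerance = 1e-10)
  expect_equal(res$or_point, exp(-0.117))
  expect_equal(res$or_low, exp(res$chosen$ci_low))
  expect_equal(res$or_high, exp(res$chosen$ci_high))
})

test_that("IVW confidence intervals attain near-nominal coverage on nulls", {
  # summary-level sampling at the estimator's asymptotic regime
  set.seed(55)
  m <- 8
  rho <- random_corr(m, seed = 21)
  ch <- chol(rho)
  bx <- runif(m, 0.2, 0.5)
  se <- rep(0.04, m)
  covered <- logical(500)
  for (r in seq_len(500)) {
    by <- drop(crossprod(ch, rnorm(m)) * se)  # null: true slope 0
    fit <- gls_ivw(make_hset(bx, by, se, rho = rho))
    covered[r] <- fit$ci_low <= 0 && 0 <= fit$ci_high
  }
  expect_gt(mean(covered), 0.92)
  expect_lt(mean(covered), 0.98)
})

test_that("planted directional pleiotropy drives Rucker towards Egger", {
  set.seed(66)
  m <- 10
  bx <- runif(m, 0.2, 0.6)
  se <- rep(0.03, m)
  chose_egger <- logical(120)
  for (r in seq_len(120)) {
    by <- 0.15 + 0.4 * bx + rnorm(m, 0, se)  # intercept = pleiotropy
    res <- fit_drug_target_mr(make_hset(bx, by, se))
    chose_egger[r] <- res$chosen$estimator == "Egger"
  }
  expect_gt(mean(chose_egger), 0.5)
})
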