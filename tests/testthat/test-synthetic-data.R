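test_that("autoregressive LD matrices follow their definition and stay PD", {
  expect_equal(unclass(simulate_ld_matrix(3, 0)), diag(3),
               ignore_attr = TRUE)
  m2 <- simulate_ld_matrix(2, 0.5)
  expect_equal(unclass(m2)[1, 2], 0.5)
  ev <- eigen(ld_r(simulate_ld_matrix(5, 0.9)), symmetric = TRUE,
              only.values = TRUE)$values
  expect_gt(min(ev), 0)
  expect_error(simulate_ld_matrix(3, 1), "decay")
  expect_error(simulate_ld_matrix(3, -0.1), "decay")
  expect_error(simulate_ld_matrix(0, 0.5), "positive integer")
})

test_that("truth parameters expose the implied total protein effect", {
  tr <- truth_params(delta = c(0.2, 0), mu = 0.5, theta = 0.4, phi_p = 0.1)
  expect_equal(tr$omega, 0.5 * 0.4 + 0.1)
  expect_error(truth_params(0.1, 0.5, 0.4, outcome_type = "binary",
                            prevalence = 1.2), "prevalence")
  expect_error(ancestry_scenario(tr, simulate_ld_matrix(2, 0), c(0.6, 0.3),
                                 100, 100), "maf")
})

test_that("individual-level simulation is seed-deterministic and honours the path model", {
  tr <- truth_params(delta = c(0.3, 0, 0.2), mu = 0.5, theta = 0.4)
  scen <- ancestry_scenario(tr, simulate_ld_matrix(3, 0.5), c(0.3, 0.2, 0.4),
                            1000, 1000)
  a <- simulate_individual_level(scen, 500, seed = 42)
  b <- simulate_individual_level(scen, 500, seed = 42)
  expect_identical(a, b)
  c <- simulate_individual_level(scen, 500, seed = 43)
  expect_false(identical(a$P, c$P))
  # with phi_p = 0 and no confounding, regressing D on P recovers mu*theta
  tr0 <- truth_params(delta = c(0.3, 0, 0.2), mu = 0.5, theta = 0.4)
  scen0 <- ancestry_scenario(tr0, simulate_ld_matrix(3, 0.5),
                             c(0.3, 0.2, 0.4), 1, 1)
  big <- simulate_individual_level(scen0, 40000, seed = 7)
  slope <- cov(big$P, big$D) / var(big$P)
  expect_lt(abs(slope - 0.2), 0.02)
  # P and X come out near unit variance
  expect_lt(abs(var(big$P) - 1), 0.08)
  expect_lt(abs(var(big$X) - 1), 0.08)
  # binary outcomes hit the target prevalence
  trb <- truth_params(delta = c(0.3, 0, 0.2), mu = 0.5, theta = -0.3,
                      outcome_type = "binary", prevalence = 0.1)
  scenb <- ancestry_scenario(trb, simulate_ld_matrix(3, 0.5),
                             c(0.3, 0.2, 0.4), 1, 1)
  simb <- simulate_individual_level(scenb, 20000, seed = 8)
  expect_lt(abs(mean(simb$D) - 0.1), 0.01)
})

test_that("null loci give uniform association statistics", {
  # delta all zero: z-scores for X are approximately standard normal
  tr <- truth_params(delta = numeric(10), mu = 0.5, theta = 0.4,
                     conf_load_p = 0.3, conf_load_x = 0.3)
  scen <- ancestry_scenario(tr, simulate_ld_matrix(10, 0.6),
                            rep(0.3, 10), 1, 1)
  zs <- unlist(lapply(1:25, function(r) {
    sim <- simulate_individual_level(scen, 1500, seed = 100 + r)
    ss <- summarize_to_gwas(sim$genotypes, sim$X, "continuous")
    ss$beta / ss$se
  }))
  ks <- suppressWarnings(ks.test(zs, "pnorm"))
  expect_gt(ks$p.value, 0.01)
})

test_that("the GWAS summarizer matches exact and null relations", {
  set.seed(5)
  g <- matrix(rbinom(600, 2, 0.4), 200, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  # trait exactly 2x genotype of variant b: beta = 2, se ~ 0
  ss <- summarize_to_gwas(g, 2 * g[, "b"], "continuous")
  expect_equal(ss$beta[2], 2, tolerance = 1e-10)
  expect_lt(ss$se[2], 1e-8)
  # monomorphic variant flagged with missing beta
  g2 <- cbind(g, mono = 2)
  ss2 <- summarize_to_gwas(g2, rnorm(200), "continuous")
  expect_true(is.na(ss2$beta[4]))
  expect_equal(ss2$eaf[4], 1)
  # independent trait: p-values uniform (fraction below 0.05 ~ 5%)
  set.seed(6)
  gg <- rbinom(150, 2, 0.3)
  hits <- vapply(1:1000, function(r) {
    ssr <- summarize_to_gwas(cbind(v = gg), rnorm(150), "continuous")
    ssr$pval < 0.05
  }, logical(1))
  expect_lt(abs(mean(hits) - 0.05), 0.025)
  # binary trait with no planted effect: mean log-OR ~ 0
  set.seed(7)
  betas <- vapply(1:60, function(r) {
    gb <- rbinom(600, 2, 0.3)
    yb <- rbinom(600, 1, 0.3)
    summarize_to_gwas(cbind(v = gb), yb, "binary")$beta
  }, numeric(1))
  expect_lt(abs(mean(betas)), 0.05)
})

test_that("realized genotype correlations track the latent LD target", {
  tr <- default_truth(n_variants = 12, causal_idx = c(3, 7))
  scen <- ancestry_scenario(tr, simulate_ld_matrix(12, 0.8),
                            rep(0.3, 12), 1, 1)
  sim <- simulate_individual_level(scen, 30000, seed = 9)
  obs <- cor(sim$genotypes)
  target <- ld_r(scen$ld)
  off <- upper.tri(obs)
  # attenuated towards zero but strongly rank-correlated with the target
  expect_gt(cor(obs[off], target[off]), 0.95)
  expect_lt(mean(abs(obs[off])), mean(abs(target[off])))
})

test_that("two-ancestry scenarios place causal variants per the sharing flag", {
  tj <- default_truth(n_variants = 20, causal_idx = c(4, 10))
  tk <- default_truth(n_variants = 20, causal_idx = c(5, 11))
  shared <- two_ancestry_scenario(tj, tk, shared_causal = TRUE,
                                  n_exposure = 400, n_outcome = 400,
                                  seed = 3)
  expect_identical(names(shared), c("EUR", "EAS"))
  expect_identical(which(shared$EUR$truth$delta != 0),
                   which(shared$EAS$truth$delta != 0))
  disjoint <- two_ancestry_scenario(tj, tk, shared_causal = FALSE,
                                    n_exposure = 400, n_outcome = 400,
                                    seed = 3)
  expect_length(intersect(which(disjoint$EUR$truth$delta != 0),
                          which(disjoint$EAS$truth$delta != 0)), 0)
  # identical seeds reproduce identical records end to end
  again <- two_ancestry_scenario(tj, tk, shared_causal = TRUE,
                                 n_exposure = 400, n_outcome = 400,
                                 seed = 3)
  expect_identical(as.data.frame(again$EUR$exposure),
                   as.data.frame(shared$EUR$exposure))
  expect_identical(unclass(again$EAS$ld), unclass(shared$EAS$ld))
})
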