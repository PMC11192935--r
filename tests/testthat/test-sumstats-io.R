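test_that("summary statistics survive a write/read round-trip at full precision", {
  set.seed(101)
  m <- 7
  ss <- make_stats(beta = rnorm(m) * 0.1, se = runif(m, 0.005, 0.05),
                   eaf = runif(m, 0.02, 0.98))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_summary_stats(ss, path)
  back <- read_summary_stats(path, trait = "trait", ancestry = "EUR",
                             outcome_type = "continuous")
  for (col in c("eaf", "beta", "se", "pval", "n")) {
    expect_equal(back[[col]], ss[[col]], tolerance = 0, info = col)
  }
  expect_identical(back$variant_id, ss$variant_id)
})

test_that("reader drops degenerate rows, normalizes alleles, honours column maps", {
  df <- data.frame(rsid = c("v1", "v2", "v3"), chr = "16",
                   bp = c(1e6, 2e6, 3e6),
                   ea = c("a", "g", "t"), oa = c("g", "a", "c"),
                   freq = c(0.2, 0.3, 0.4), b = c(0.1, 0.2, 0.3),
                   stderr = c(0.01, 0, 0.02))
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  cmap <- c(variant_id = "rsid", chrom = "chr", pos = "bp",
            effect_allele = "ea", other_allele = "oa", eaf = "freq",
            beta = "b", se = "stderr")
  expect_message(
    ss <- read_summary_stats(path, trait = "t", column_map = cmap),
    "dropped 1")
  expect_equal(nrow(ss), 2L)                      # se = 0 row gone
  expect_identical(ss$effect_allele, c("A", "T")) # uppercased
  # p recomputed from beta/se when absent
  expect_equal(ss$pval, 2 * pnorm(-abs(ss$beta / ss$se)))
  # unmapped required column is a configuration error
  expect_error(read_summary_stats(path, trait = "t"), "column_map")
})

test_that("harmonization flips swapped alleles and drops irreconcilable ones", {
  expo <- make_stats(beta = c(0.1, 0.1, 0.1), se = rep(0.01, 3),
                     eaf = c(0.3, 0.3, 0.3),
                     effect_allele = c("A", "A", "A"),
                     other_allele = c("G", "G", "G"))
  out_df <- as.data.frame(expo)
  out_df$beta <- c(0.2, 0.2, 0.2)
  # v1 identical, v2 swapped, v3 irreconcilable (A/T vs exposure A/G)
  out_df$effect_allele <- c("A", "G", "A")
  out_df$other_allele <- c("G", "A", "T")
  out_df$eaf <- c(0.3, 0.3, 0.3)
  outc <- summary_stats(out_df, trait = "out", ancestry = "EUR",
                        outcome_type = "continuous")
  h <- harmonize(expo, outc)
  expect_identical(h$outcome$variant_id, c("v001", "v002"))
  expect_equal(h$outcome$beta, c(0.2, -0.2))
  expect_equal(h$outcome$eaf, c(0.3, 0.7))
  expect_identical(
    h$report$action[h$report$variant_id == "v003"], "drop_irreconcilable")
  # orientation involution: harmonizing the harmonized pair is a no-op
  h2 <- harmonize(h$exposure, h$outcome)
  expect_equal(as.data.frame(h2$outcome), as.data.frame(h$outcome))
  expect_equal(as.data.frame(h2$exposure), as.data.frame(h$exposure))
})

test_that("palindromic variants follow the configured policy", {
  expo <- make_stats(beta = c(0.1, 0.1), se = rep(0.01, 2),
                     eaf = c(0.48, 0.2),
                     effect_allele = c("A", "A"), other_allele = c("T", "T"))
  out_df <- as.data.frame(expo)
  out_df$eaf <- c(0.49, 0.8)  # v1 ambiguous; v2 clearly opposite side
  outc <- summary_stats(out_df, trait = "out", outcome_type = "continuous")
  h <- harmonize(expo, outc, palindromic_policy = "drop")
  expect_identical(h$report$action, c("drop_palindromic", "flip"))
  expect_equal(h$outcome$beta, -0.1)
  expect_equal(h$outcome$eaf, 0.2)
  h_keep <- harmonize(expo, outc, palindromic_policy = "keep")
  expect_identical(h_keep$report$action, c("keep", "keep"))
  # disjoint variant lists are an error naming both traits
  expo2 <- make_stats(beta = 0.1, se = 0.01, ids = "zzz")
  expect_error(harmonize(expo2, outc), "no shared variants")
})

test_that("dosage LD matches a naive per-pair correlation oracle", {
  set.seed(42)
  g <- matrix(rbinom(40 * 4, 2, 0.4), 40, 4,
              dimnames = list(NULL, paste0("v", 1:4)))
  ld <- compute_ld_from_dosages(g)
  # brute-force double loop
  for (i in 1:4) for (j in 1:4) {
    expect_equal(unclass(ld)[i, j], cor(g[, i], g[, j]), tolerance = 1e-12)
  }
  # identical columns give r = 1; 2 - g coding gives r = -1
  g2 <- cbind(a = g[, 1], b = g[, 1], c = 2 - g[, 1])
  ld2 <- compute_ld_from_dosages(g2)
  expect_equal(unclass(ld2)["a", "b"], 1)
  expect_equal(unclass(ld2)["a", "c"], -1)
  # monomorphic column is a hard error
  g3 <- cbind(g, mono = rep(1, 40))
  expect_error(compute_ld_from_dosages(g3), "monomorphic")
})

test_that("align_to_ld subsets, reorders and sign-flips allele mismatches", {
  ss <- make_stats(beta = c(0.1, 0.2, 0.3), se = rep(0.01, 3),
                   ids = c("b", "c", "a"))
  r <- random_corr(4, seed = 5)
  ld <- ld_matrix(r, variant_ids = c("a", "b", "c", "d"),
                  effect_alleles = c("A", "A", "G", "A"))
  out <- align_to_ld(ss, ld)
  expect_identical(out$stats$variant_id, c("b", "c", "a"))
  expect_identical(ld_ids(out$ld), c("b", "c", "a"))
  # variant c has LD reference allele G = stats other allele -> flipped
  expect_equal(unclass(out$ld)["b", "c"], -r[2, 3])
  expect_equal(unclass(out$ld)["c", "a"], -r[3, 1])
  expect_equal(unclass(out$ld)["b", "a"], r[2, 1])
  expect_equal(unname(diag(unclass(out$ld))), rep(1, 3))
  # ld_matrix invariants hold after random flips
  expect_s3_class(out$ld, "ld_matrix")
  # disjoint ids error
  ss2 <- make_stats(beta = 0.1, se = 0.01, ids = "zzz")
  expect_error(align_to_ld(ss2, ld), "no shared variants")
})

test_that("LD matrices round-trip through their text format", {
  ld <- ld_matrix(random_corr(5, seed = 9))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ld_matrix(ld, path)
  back <- read_ld_matrix(path)
  expect_identical(ld_ids(back), ld_ids(ld))
  expect_equal(unclass(back), unclass(ld), tolerance = 1e-15,
               ignore_attr = TRUE)
})
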