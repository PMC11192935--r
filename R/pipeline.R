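#' Default run configuration for the two-ancestry pipeline
#'
#' A single structured list drives the simulate / run / report pipeline.
#' Unknown keys are rejected by [validate_run_config()] so silent typos
#' cannot change an analysis. Per-ancestry fields are length-2 vectors
#' ordered as `labels`.
#'
#' @return A named list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    seed = 1L,
    out_dir = tempfile("crossmr_run_"),
    labels = c("EUR", "EAS"),
    n_variants = 60L,
    decay = c(0.8, 0.7),
    n_exposure = c(10000L, 10000L),
    n_outcome = c(10000L, 10000L),
    causal_idx = c(10L, 30L, 50L),
    delta_causal = c(0.25, 0.25),
    mu = c(0.5, 0.5),
    conf_load = 0.3,
    exposure_name = "biomarker",
    outcomes = list(
      list(name = "trait_md", outcome_type = "continuous",
           theta = c(0.4, 0.4), phi_p = c(0, 0)),
      list(name = "disease_or", outcome_type = "binary",
           theta = c(-0.3, -0.3), phi_p = c(0, 0), prevalence = 0.1),
      list(name = "null_trait", outcome_type = "continuous",
           theta = c(0, 0), phi_p = c(0, 0))),
    region = list(chrom = "16", start = 56995762, end = 57017757),
    flank_bp = 50000,
    maf_min = 0.01,
    f_min = 15,
    r2_max = 0.3,
    palindromic_policy = "drop",
    coloc = list(p1 = 1e-4, p2 = 1e-4, p12 = 1e-6, prior_sd = NULL),
    multiplicity = list(n_traits = NULL, nominal_alpha = 0.05),
    estimator = "rucker",
    overdispersion = FALSE),
    class = "run_config")
}

#' Validate and complete a run configuration
#'
#' Merges user overrides onto [default_run_config()]; unknown keys (at the
#' top level and within `region`, `coloc`, `multiplicity`) are rejected.
#'
#' @param config a named list of overrides, a `run_config`, or a path to a
#'   YAML file holding one.
#' @return A complete `run_config`.
#' @export
validate_run_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop2("config: no such file: ", config)
    config <- yaml::read_yaml(config)
  }
  defaults <- default_run_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    stop2("config: unknown key(s): ", paste(unknown, collapse = ", "))
  }
  for (sub in c("region", "coloc", "multiplicity")) {
    if (!is.null(config[[sub]])) {
      bad <- setdiff(names(config[[sub]]), names(defaults[[sub]]))
      if (length(bad)) {
        stop2("config: unknown key(s) in ", sub, ": ",
              paste(bad, collapse = ", "))
      }
    }
  }
  cfg <- utils::modifyList(defaults, config)
  for (field in c("decay", "n_exposure", "n_outcome", "delta_causal", "mu")) {
    cfg[[field]] <- rep_len(cfg[[field]], 2L)
  }
  if (!is_count(cfg$n_variants)) stop2("config: n_variants must be a positive integer")
  if (length(cfg$outcomes) < 1L) stop2("config: at least one outcome required")
  structure(cfg, class = "run_config")
}

cfg_region <- function(cfg) {
  gene_region(cfg$region$chrom, cfg$region$start, cfg$region$end,
              flank = cfg$flank_bp)
}

cfg_truth <- function(cfg, ancestry_idx, outcome_spec) {
  delta <- numeric(cfg$n_variants)
  delta[cfg$causal_idx] <- cfg$delta_causal[ancestry_idx]
  truth_params(delta = delta, mu = cfg$mu[ancestry_idx],
               theta = rep_len(outcome_spec$theta, 2L)[ancestry_idx],
               phi_p = rep_len(outcome_spec$phi_p %||% 0, 2L)[ancestry_idx],
               conf_load_p = cfg$conf_load, conf_load_x = cfg$conf_load,
               conf_load_d = cfg$conf_load,
               outcome_type = outcome_spec$outcome_type,
               prevalence = outcome_spec$prevalence %||% 0.1)
}

pipeline_paths <- function(cfg) {
  data_dir <- file.path(cfg$out_dir, "data")
  list(data_dir = data_dir,
       results_dir = file.path(cfg$out_dir, "results"),
       exposure = function(label) file.path(
         data_dir, paste0("exposure_", label, ".tsv")),
       outcome = function(name, label) file.path(
         data_dir, paste0("outcome_", name, "_", label, ".tsv")),
       ld = function(label) file.path(data_dir, paste0("ld_", label, ".tsv")),
       truth = file.path(data_dir, "truth.json"))
}

#' Simulate a complete two-ancestry study to disk
#'
#' Writes, under `config$out_dir/data`, per-ancestry exposure (biomarker)
#' summary statistics, one outcome file per configured trait, the LD
#' matrix recomputed from the simulated exposure genotypes, and a truth
#' JSON sidecar for downstream recovery checks. Identical configurations
#' and seeds give byte-identical files.
#'
#' @param config overrides for [default_run_config()] (list, `run_config`
#'   or YAML path).
#' @return The validated `run_config`, invisibly.
#' @export
pipeline_simulate <- function(config = list()) {
  cfg <- validate_run_config(config)
  paths <- pipeline_paths(cfg)
  dir.create(paths$data_dir, recursive = TRUE, showWarnings = FALSE)
  variants <- default_variants(cfg$n_variants)
  truth_sidecar <- list()
  for (i in 1:2) {
    label <- cfg$labels[i]
    set.seed(child_seed(cfg$seed, 10 * i))
    maf <- stats::runif(cfg$n_variants, 0.05, 0.5)
    ld_target <- simulate_ld_matrix(cfg$n_variants, cfg$decay[i])
    base_truth <- cfg_truth(cfg, i, cfg$outcomes[[1L]])
    scen <- ancestry_scenario(base_truth, ld_target, maf,
                              cfg$n_exposure[i], cfg$n_outcome[i],
                              label = label, variants = variants)
    expo <- simulate_individual_level(scen, cfg$n_exposure[i],
                                      seed = child_seed(cfg$seed, 100 * i))
    ss_x <- summarize_to_gwas(expo$genotypes, expo$X, "continuous",
                              variants = variants,
                              trait_name = cfg$exposure_name,
                              ancestry = label)
    write_summary_stats(ss_x, paths$exposure(label))
    poly <- colMeans(expo$genotypes) / 2
    keep <- poly > 0 & poly < 1
    ld_obs <- compute_ld_from_dosages(
      expo$genotypes[, keep, drop = FALSE],
      variant_ids = colnames(expo$genotypes)[keep],
      effect_alleles = variants$effect_allele[keep])
    write_ld_matrix(ld_obs, paths$ld(label))
    for (k in seq_along(cfg$outcomes)) {
      spec <- cfg$outcomes[[k]]
      truth_k <- cfg_truth(cfg, i, spec)
      scen_k <- ancestry_scenario(truth_k, ld_target, maf,
                                  cfg$n_exposure[i], cfg$n_outcome[i],
                                  label = label, variants = variants)
      outc <- simulate_individual_level(
        scen_k, cfg$n_outcome[i],
        seed = child_seed(cfg$seed, 100 * i + 1000 * k))
      ss_d <- summarize_to_gwas(outc$genotypes, outc$D, spec$outcome_type,
                                variants = variants,
                                trait_name = spec$name, ancestry = label)
      write_summary_stats(ss_d, paths$outcome(spec$name, label))
      truth_sidecar[[label]][[spec$name]] <-
        list(mu = truth_k$mu, theta = truth_k$theta, phi_p = truth_k$phi_p,
             omega = truth_k$omega, omega_bw = truth_k$omega / truth_k$mu,
             outcome_type = truth_k$outcome_type)
    }
  }
  jsonlite::write_json(truth_sidecar, paths$truth, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(cfg)
}

read_stage <- function(stage, path, reader, ...) {
  if (!file.exists(path)) {
    stop2(stage, ": missing input file: ", path)
  }
  tryCatch(reader(path, ...),
           error = function(e) stop2(stage, ": ", conditionMessage(e)))
}

#' Run the full two-ancestry analysis on simulated (or compatible) files
#'
#' For each ancestry and outcome: select instruments (harmonize, align to
#' LD, region, MAF/F, clump) and fit the GLS MR with Rucker selection;
#' then colocalize the exposure signal across ancestries and run the
#' interaction tests with the multiplicity plan. Results and filter logs
#' are written under `config$out_dir/results`.
#'
#' @param config overrides for [default_run_config()]; input files are
#'   expected where [pipeline_simulate()] put them.
#' @return A result bundle (list of class `pipeline_bundle`) with
#'   `mr_results`, `mr_table`, `interactions`, `interaction_table`,
#'   `coloc`, `plan`, `filter_logs`, `truth` (if the sidecar exists) and
#'   `config`.
#' @export
pipeline_run <- function(config = list()) {
  cfg <- validate_run_config(config)
  paths <- pipeline_paths(cfg)
  dir.create(paths$results_dir, recursive = TRUE, showWarnings = FALSE)
  region <- cfg_region(cfg)

  exposures <- list()
  lds <- list()
  for (i in 1:2) {
    label <- cfg$labels[i]
    exposures[[label]] <- read_stage(
      "exposure", paths$exposure(label), read_summary_stats,
      trait = cfg$exposure_name, ancestry = label,
      outcome_type = "continuous")
    lds[[label]] <- read_stage("ld", paths$ld(label), read_ld_matrix)
  }

  mr_results <- list()
  filter_logs <- list()
  for (spec in cfg$outcomes) {
    for (i in 1:2) {
      label <- cfg$labels[i]
      outc <- read_stage("outcome", paths$outcome(spec$name, label),
                         read_summary_stats, trait = spec$name,
                         ancestry = label,
                         outcome_type = spec$outcome_type)
      sel <- tryCatch(
        select_instruments(exposures[[label]], outc, lds[[label]], region,
                           maf_min = cfg$maf_min, f_min = cfg$f_min,
                           r2_max = cfg$r2_max,
                           palindromic_policy = cfg$palindromic_policy),
        error = function(e) stop2("instruments[", spec$name, ", ", label,
                                  "]: ", conditionMessage(e)))
      fit <- tryCatch(
        fit_drug_target_mr(sel$hset, estimator = cfg$estimator,
                           overdispersion = cfg$overdispersion),
        error = function(e) stop2("mr[", spec$name, ", ", label, "]: ",
                                  conditionMessage(e)))
      key <- paste(spec$name, label, sep = ".")
      mr_results[[key]] <- fit
      filter_logs[[key]] <- sel$log
    }
  }

  coloc_res <- tryCatch(
    cross_ancestry_coloc(exposures[[1L]], exposures[[2L]], region,
                         priors = coloc_priors(cfg$coloc$p1, cfg$coloc$p2,
                                               cfg$coloc$p12),
                         maf_min = cfg$maf_min,
                         prior_sd = cfg$coloc$prior_sd),
    error = function(e) stop2("coloc: ", conditionMessage(e)))

  n_traits <- cfg$multiplicity$n_traits %||% length(cfg$outcomes)
  plan <- build_multiplicity_plan(n_traits, cfg$multiplicity$nominal_alpha)
  interactions <- lapply(cfg$outcomes, function(spec) {
    interaction_test(mr_results[[paste(spec$name, cfg$labels[1], sep = ".")]],
                     mr_results[[paste(spec$name, cfg$labels[2], sep = ".")]],
                     plan = plan)
  })
  names(interactions) <- vapply(cfg$outcomes, `[[`, "", "name")

  mr_tab <- mr_results_table(mr_results)
  int_tab <- interaction_results_table(interactions)
  utils::write.table(mr_tab, file.path(paths$results_dir, "mr_results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(int_tab,
                     file.path(paths$results_dir, "interactions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_coloc_json(coloc_res, file.path(paths$results_dir, "coloc.json"))
  jsonlite::write_json(lapply(filter_logs, unclass),
                       file.path(paths$results_dir, "filter_logs.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  truth <- if (file.exists(paths$truth)) {
    jsonlite::read_json(paths$truth, simplifyVector = TRUE)
  } else NULL
  structure(list(mr_results = mr_results, mr_table = mr_tab,
                 interactions = interactions, interaction_table = int_tab,
                 coloc = coloc_res, plan = plan, filter_logs = filter_logs,
                 truth = truth, config = cfg),
            class = "pipeline_bundle")
}

#' Render a result bundle as human-readable tables
#'
#' Produces a markdown forest-style summary (one block per trait with
#' ancestry-specific estimates, the interaction p-value with its
#' corrected-alpha flag, and the direction class) plus the flat TSV twin.
#' Files `report.md` and `report.tsv` are written under the bundle's
#' results directory.
#'
#' @param bundle a `pipeline_bundle` from [pipeline_run()].
#' @return The markdown text, invisibly (also printed).
#' @export
pipeline_report <- function(bundle) {
  stopifnot(inherits(bundle, "pipeline_bundle"))
  cfg <- bundle$config
  lines <- c("# Two-ancestry drug-target MR report", "")
  lines <- c(lines, sprintf(
    "Cross-ancestry colocalization of the %s signal: PP.H4 = %.3f (%s)",
    cfg$exposure_name, bundle$coloc$pp["pp_h4"],
    if (isTRUE(bundle$coloc$colocalized)) "colocalized" else
      "not colocalized"), "")
  lines <- c(lines, sprintf(
    "Interaction alpha corrected for %d traits: %.3g", bundle$plan$n_traits,
    bundle$plan$corrected_alpha), "")
  fmt_est <- function(res) {
    ch <- res$chosen
    if (identical(res$effect_scale, "odds-ratio")) {
      sprintf("OR %.3f (95%% CI %.3f-%.3f), p = %.3g [%s]",
              res$or_point, res$or_low, res$or_high, ch$pval, ch$estimator)
    } else {
      sprintf("MD %.3f (95%% CI %.3f-%.3f), p = %.3g [%s]",
              ch$slope, ch$ci_low, ch$ci_high, ch$pval, ch$estimator)
    }
  }
  for (spec in cfg$outcomes) {
    it <- bundle$interactions[[spec$name]]
    lines <- c(lines, sprintf("## %s (%s)", spec$name, spec$outcome_type))
    for (label in cfg$labels) {
      res <- bundle$mr_results[[paste(spec$name, label, sep = ".")]]
      lines <- c(lines, sprintf("- %s: %s", label, fmt_est(res)))
    }
    lines <- c(lines, sprintf(
      "- interaction: p = %.3g%s, direction %s", it$pval,
      if (isTRUE(it$significant_at_corrected_alpha)) " *" else "",
      it$direction_class), "")
  }
  text <- paste(lines, collapse = "\n")
  results_dir <- pipeline_paths(cfg)$results_dir
  if (dir.exists(results_dir)) {
    writeLines(text, file.path(results_dir, "report.md"))
    utils::write.table(bundle$interaction_table,
                       file.path(results_dir, "report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  cat(text, "\n")
  invisible(text)
}
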