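# End-to-end orchestration: simulate (or read) -> QC -> GWAS -> instruments
# -> one-sample MR -> two-sample MR -> report bundle.

.pipeline_defaults <- function() {
  list(
    simulation = list(
      n_exposure_cohort = 5902L, n_outcome_cohorts = c(3693L, 1816L),
      theta = 0.7, alpha_pleiotropy = 0,
      confounder_exposure = 0.15, confounder_outcome = 0.25,
      exposure_noise_sd = 0.2, missing_rate = 0.002
    ),
    qc = list(max_missing = 0.01, hwe_alpha = 1e-6),
    instruments = list(p_threshold = 4e-8, r2_threshold = 0.01),
    estimators = list(ivw_model = "fixed", n_boot = 2000L,
                      tsls_boot = 0L),
    covariates = c("age", "sex", "area"),
    seed = 1L
  )
}

.pipeline_provenance <- tibble::tribble(
  ~key, ~default, ~rationale,
  "simulation.n_exposure_cohort", "5902",
  "exposure-cohort size the pipeline emulates (KARE-style)",
  "simulation.n_outcome_cohorts", "3693, 1816",
  "two outcome cohorts (HEXA- and CAVAS-style sizes)",
  "simulation.theta", "0.7",
  "default causal log-odds of MetS per SD log-Hcy, near published two-sample estimates",
  "qc.max_missing", "0.01", "array-QC convention: missing rate > 1% removed",
  "qc.hwe_alpha", "1e-6", "array-QC convention: HWE p < 1e-6 removed",
  "instruments.p_threshold", "4e-8",
  "Bonferroni-corrected genome-wide significance, strict inequality",
  "instruments.r2_threshold", "0.01",
  "LD-clumping independence threshold (a looser 0.1 convention also circulates; both supported)",
  "estimators.ivw_model", "fixed",
  "fixed-effect IVW default; multiplicative random effects suggested when Q p < 0.05",
  "estimators.n_boot", "2000",
  "weighted-median parametric bootstrap draws",
  "covariates", "age, sex, area", "standard adjustment set for these cohorts"
)

#' Validate a pipeline configuration
#'
#' Accepts a YAML file path, YAML text or a nested list; checks it against
#' the schema, fills defaults and returns a `pipeline_config` whose
#' `"provenance"` attribute states the rationale for every defaulted
#' value. Unknown keys and out-of-range thresholds are reported together
#' in one aggregated error.
#'
#' @param config NULL (all defaults), a path to a YAML file, a YAML
#'   string, or a list.
#' @return A validated `pipeline_config` list.
#' @examples
#' cfg <- validate_config(list(seed = 7, instruments = list(
#'   r2_threshold = 0.1)))
#' attr(cfg, "provenance")
#' @export
validate_config <- function(config = NULL) {
  raw <- if (is.null(config)) {
    list()
  } else if (is.list(config)) {
    config
  } else if (is.character(config) && length(config) == 1L) {
    if (file.exists(config)) yaml::read_yaml(config) else
      yaml::yaml.load(config)
  } else {
    abort("`config` must be NULL, a list, a YAML path or YAML text",
          class = "hcymr_validation_error")
  }
  raw <- raw %||% list()
  defaults <- .pipeline_defaults()
  errors <- character()

  unknown_top <- setdiff(names(raw), c(names(defaults), "paths"))
  if (length(unknown_top)) {
    errors <- c(errors, paste0("unknown key(s): ",
                               paste(unknown_top, collapse = ", ")))
  }
  for (blk in intersect(names(raw), names(defaults))) {
    if (is.list(defaults[[blk]]) && !is.null(names(defaults[[blk]]))) {
      unk <- setdiff(names(raw[[blk]]), names(defaults[[blk]]))
      if (length(unk)) {
        errors <- c(errors, paste0("unknown key(s) in ", blk, ": ",
                                   paste(unk, collapse = ", ")))
      }
    }
  }
  cfg <- utils::modifyList(defaults, raw[intersect(names(raw),
                                                   names(defaults))])
  if (!is.null(raw$paths)) cfg$paths <- raw$paths
  # numeric strings from YAML ("4e-8") are parsed to numbers
  for (k in c("p_threshold", "r2_threshold")) {
    cfg$instruments[[k]] <- suppressWarnings(
      as.numeric(cfg$instruments[[k]]))
  }
  if (!is.null(cfg$paths) && !is.null(raw$simulation)) {
    errors <- c(errors,
                "exactly one of `paths` and `simulation` may be specified")
  }
  chk <- function(cond, msg) if (!isTRUE(cond)) errors <<- c(errors, msg)
  chk(is.numeric(cfg$qc$max_missing) && cfg$qc$max_missing >= 0 &&
        cfg$qc$max_missing <= 1, "qc.max_missing must be in [0,1]")
  chk(is.numeric(cfg$qc$hwe_alpha) && cfg$qc$hwe_alpha > 0 &&
        cfg$qc$hwe_alpha <= 1, "qc.hwe_alpha must be in (0,1]")
  chk(is.finite(cfg$instruments$p_threshold) &&
        cfg$instruments$p_threshold > 0 &&
        cfg$instruments$p_threshold <= 1,
      "instruments.p_threshold must be in (0,1]")
  chk(is.finite(cfg$instruments$r2_threshold) &&
        cfg$instruments$r2_threshold > 0 &&
        cfg$instruments$r2_threshold <= 1,
      "instruments.r2_threshold must be in (0,1]")
  chk(is.numeric(cfg$seed) && cfg$seed == floor(cfg$seed),
      "seed must be an integer")
  if (length(errors)) {
    abort(paste0("invalid pipeline configuration:\n- ",
                 paste(errors, collapse = "\n- ")),
          class = "hcymr_config_error")
  }
  structure(cfg, provenance = .pipeline_provenance,
            class = "pipeline_config")
}

#' Run the full MR pipeline
#'
#' Executes the stages in fixed order — simulate (three cohorts: one
#' one-sample cohort with exposure and outcome, two outcome-only cohorts),
#' genotype QC, exposure GWAS, instrument selection and LD clumping,
#' F-statistic and confounder diagnostics, one-sample MR (Wald ratio on
#' the strongest instrument, weighted-GRS 2SLS), outcome GWAS per cohort,
#' and two-sample MR with sensitivity statistics. Identical config and
#' seed give identical numeric outputs. When `output_dir` is given, each
#' stage writes its TSV/JSON artifact plus a manifest recording package
#' version, seed and a config hash.
#'
#' @param config A `pipeline_config` (see [validate_config()]), or
#'   anything it accepts.
#' @param output_dir Optional directory for artifacts.
#' @param quiet Suppress per-stage log lines.
#' @return A `pipeline_result` list bundling every stage's output.
#' @export
run_pipeline <- function(config = NULL, output_dir = NULL,
                         quiet = FALSE) {
  cfg <- if (inherits(config, "pipeline_config")) config else
    validate_config(config)
  log_stage <- function(stage, ...) {
    if (!quiet) {
      kv <- paste(purrr::imap_chr(list(...),
                                  ~ paste0(.y, "=", .x)),
                  collapse = " ")
      message(sprintf("[%s] stage=%s %s",
                      format(Sys.time(), "%H:%M:%S"), stage, kv))
    }
  }
  seed <- as.integer(cfg$seed)
  sim <- cfg$simulation

  make_cohort <- function(n, stage_seed) {
    simulate_cohort(sim_config(
      n_samples = n, theta = sim$theta,
      alpha_pleiotropy = sim$alpha_pleiotropy,
      confounder_exposure = sim$confounder_exposure,
      confounder_outcome = sim$confounder_outcome,
      exposure_noise_sd = sim$exposure_noise_sd,
      missing_rate = sim$missing_rate, seed = stage_seed))
  }
  one <- make_cohort(sim$n_exposure_cohort, derive_seed(seed, "pipeline"))
  outc <- purrr::map2(
    sim$n_outcome_cohorts, c("cohort_two", "cohort_three"),
    function(n, st) make_cohort(n, derive_seed(seed, st)))
  log_stage("simulate", n_exposure = sim$n_exposure_cohort,
            n_outcome = paste(sim$n_outcome_cohorts, collapse = "+"))

  qc <- qc_filter(one$genotypes, cfg$qc$max_missing, cfg$qc$hwe_alpha)
  log_stage("qc", input = qc$report$n_input,
            retained = length(qc$report$retained))

  covs <- one$phenotypes[cfg$covariates]
  expo_gwas <- linear_assoc(qc$genotypes, one$phenotypes$log_hcy,
                            covariates = covs, trait = "exposure")
  log_stage("gwas_exposure", n_variants = nrow(expo_gwas))

  sel <- select_instruments(expo_gwas, cfg$instruments$p_threshold)
  clump <- ld_clump(sel, qc$genotypes, cfg$instruments$r2_threshold)
  instr_ids <- clump$retained
  log_stage("instruments", candidates = nrow(sel),
            retained = length(instr_ids))
  if (!length(instr_ids)) {
    abort("no instruments retained; cannot continue",
          class = "hcymr_empty_error")
  }

  dos <- geno_dosage(qc$genotypes)[, instr_ids, drop = FALSE]
  fstat <- f_statistic(one$phenotypes$log_hcy, dos, covs)
  screen <- confounder_screen(geno_subset(qc$genotypes, instr_ids),
                              one$phenotypes, adjust = cfg$covariates)
  log_stage("diagnostics", f = sprintf("%.1f", fstat$f),
            confounder_flags = sum(screen$flagged))

  # MR estimates are reported per SD of log-Hcy: rescale the exposure
  # GWAS (run on the log scale, the unit published instrument effects use)
  # by the cohort SD before the MR stages.
  expo_sd <- sd(one$phenotypes$log_hcy)
  expo_gwas_sd <- dplyr::mutate(expo_gwas, beta = beta / expo_sd,
                                se = se / expo_sd)

  # one-sample MR: weighted GRS (exposure-GWAS weights) as the instrument
  weights <- setNames(
    expo_gwas$beta[match(instr_ids, expo_gwas$snp_id)], instr_ids)
  grs <- build_grs(qc$genotypes, weights, model = "additive")
  dat1 <- dplyr::bind_cols(one$phenotypes, grs["grs"])
  one_mr <- tsls(dat1, "log_hcy", "mets", "grs",
                 covariates = cfg$covariates,
                 boot = cfg$estimators$tsls_boot, seed = seed)
  top_id <- sel$snp_id[1]
  out_gwas_one <- logistic_assoc(
    geno_subset(qc$genotypes, instr_ids), one$phenotypes$mets,
    covariates = covs, trait = "outcome")
  wald_top <- wald_ratio(
    expo_gwas_sd$beta[expo_gwas_sd$snp_id == top_id],
    expo_gwas_sd$se[expo_gwas_sd$snp_id == top_id],
    out_gwas_one$beta[out_gwas_one$snp_id == top_id],
    out_gwas_one$se[out_gwas_one$snp_id == top_id])
  log_stage("onesample", tsls = sprintf("%.3f", one_mr$estimate),
            wald_top = sprintf("%.3f", wald_top$estimate))

  # outcome GWAS in the independent cohorts, then two-sample MR
  out_stats <- purrr::map(outc, function(co) {
    q <- qc_filter(co$genotypes, cfg$qc$max_missing, cfg$qc$hwe_alpha)
    keep <- intersect(instr_ids, geno_variants(q$genotypes)$snp_id)
    logistic_assoc(geno_subset(q$genotypes, keep), co$phenotypes$mets,
                   covariates = co$phenotypes[cfg$covariates],
                   trait = "outcome")
  })
  expo_sel <- expo_gwas_sd[expo_gwas_sd$snp_id %in% instr_ids, ]
  two <- run_twosample(expo_sel, out_stats,
                       ivw_model = cfg$estimators$ivw_model,
                       n_boot = cfg$estimators$n_boot, seed = seed)
  log_stage("twosample", k = nrow(two$instruments),
            ivw = sprintf("%.3f", two$results$estimate[
                            grepl("^ivw", two$results$method)]))

  result <- structure(list(
    config = cfg,
    qc_report = qc$report,
    exposure_gwas = expo_gwas,
    selection = sel, clump = clump, f_stat = fstat,
    confounder_screen = screen,
    onesample = dplyr::bind_rows(one_mr, wald_top),
    outcome_gwas = out_stats,
    twosample = two,
    manifest = list(
      package = "hcymr",
      version = as.character(utils::packageVersion("hcymr")),
      seed = seed,
      config_hash = rlang::hash(unclass(cfg)),
      n_cohorts = 1L + length(outc))
  ), class = "pipeline_result")

  if (!is.null(output_dir)) {
    write_pipeline_artifacts(result, one, outc, output_dir)
    log_stage("write", dir = output_dir)
  }
  result
}

write_pipeline_artifacts <- function(result, one, outc, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(output_dir, f)
  write_genotypes(one$genotypes, p("exposure_cohort_genotypes.tsv"))
  write_phenotypes(one$phenotypes, p("exposure_cohort_phenotypes.tsv"))
  readr::write_tsv(result$exposure_gwas, p("exposure_gwas.tsv"))
  readr::write_tsv(result$selection, p("selected_instruments.tsv"))
  readr::write_tsv(result$confounder_screen, p("confounder_screen.tsv"))
  readr::write_tsv(as_tibble(result$onesample), p("onesample_mr.tsv"))
  readr::write_tsv(as_tibble(result$twosample$results),
                   p("twosample_mr.tsv"))
  readr::write_tsv(result$twosample$instruments, p("instruments.tsv"))
  jsonlite::write_json(
    list(manifest = result$manifest,
         qc = result$qc_report[c("n_input", "n_removed_missingness",
                                 "n_removed_monomorphic",
                                 "n_removed_hwe")],
         f_stat = result$f_stat$f,
         clump = list(retained = result$clump$retained,
                      threshold = result$clump$threshold),
         heterogeneity = result$twosample$Q,
         i2_gx = result$twosample$i2_gx),
    p("diagnostics.json"), auto_unbox = TRUE, digits = NA)
  invisible(result)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$qc_report)
  cat(sprintf("instruments retained: %s (first-stage F = %.1f)\n",
              paste(x$clump$retained, collapse = ", "), x$f_stat$f))
  cat("one-sample MR:\n")
  print(as.data.frame(x$onesample[, c("method", "estimate", "ci_low",
                                      "ci_high", "p")]),
        row.names = FALSE, digits = 4)
  cat("two-sample MR:\n")
  print(x$twosample)
  invisible(x)
}
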