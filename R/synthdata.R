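#' Default five-variant homocysteine instrument panel
#'
#' The five genome-wide significant homocysteine-associated variants used
#' throughout the package as the default simulated instrument set
#' (rs12567136/CLCN6, rs1801133/MTHFR, rs2336377, rs1624230/KNG1,
#' rs1836883/NOX4) with their per-allele effects on natural-log
#' homocysteine. Effect-allele frequencies are approximate East-Asian
#' values; the published source does not print them.
#'
#' @return A tibble with `snp_id`, `chr`, `pos`, `effect_allele`,
#'   `other_allele`, `freq` and `beta` (log-umol/L per effect allele).
#' @export
default_hcy_variants <- function() {
  tibble(
    snp_id = c("rs12567136", "rs1801133", "rs2336377",
               "rs1624230", "rs1836883"),
    chr = c(1L, 1L, 1L, 3L, 11L),
    pos = c(11866183L, 11856378L, 3666258L, 186448785L, 89322734L),
    effect_allele = c("A", "G", "G", "C", "T"),
    other_allele = c("G", "A", "A", "T", "C"),
    freq = c(0.85, 0.66, 0.80, 0.55, 0.35),
    beta = c(-0.058, -0.039, -0.045, -0.027, 0.029)
  )
}

#' Simulation configuration for a synthetic cohort
#'
#' Bundles the full generative specification of a KoGES-style cohort:
#' genotypes in Hardy-Weinberg proportions, additive per-allele effects on
#' log-homocysteine (log-Hcy), a latent standard-normal confounder acting on
#' both exposure and outcome, five metabolic-syndrome (MetS) component
#' liabilities sharing the exposure effect equally, and optional direct
#' SNP-to-outcome (pleiotropic) effects. `theta` is the causal estimand:
#' the marginal log-odds of MetS per 1 SD increase in log-Hcy induced
#' genetically. The per-component liability slope is calibrated numerically
#' so that `theta` has exactly this interpretation (see the methods
#' vignette).
#'
#' @param n_samples Cohort size (default 5902, the exposure-cohort size the
#'   pipeline emulates).
#' @param variants Tibble of variant metadata with `snp_id`,
#'   `effect_allele`, `other_allele`, `freq` (effect-allele frequency,
#'   strictly inside (0,1)).
#' @param beta_exposure Per-allele effect of each variant on log-Hcy
#'   (log-umol/L per effect allele); defaults to the `variants$beta` column.
#' @param theta Causal effect of 1 SD log-Hcy on MetS, log-odds per SD.
#' @param alpha_pleiotropy Direct per-allele SNP effect on each MetS
#'   component liability (log-odds per allele); scalar or one per variant.
#' @param confounder_exposure,confounder_outcome Effect of the latent
#'   confounder U ~ N(0,1) on log-Hcy and on each component liability
#'   (logit scale).
#' @param exposure_intercept Mean log-Hcy at reference covariates
#'   (log-umol/L; default 2.45 so the cohort median sits near 2.56).
#' @param exposure_noise_sd Residual SD of log-Hcy (> 0).
#' @param age_effect,sex_effect Effects of age (per year, centred at 58) and
#'   male sex on log-Hcy; observed covariates influence the exposure only.
#' @param component_prevalence Marginal prevalence targets for the five
#'   MetS components (central obesity, high triglycerides, low HDL, high
#'   blood pressure, high fasting glucose) — the liability cutoffs on the
#'   probability scale.
#' @param missing_rate Per-entry probability of a missing dosage.
#' @param ld_blocks Optional tibble (`size`, `freq`, `r2`) describing
#'   correlated variant blocks; when given, genotypes come from
#'   [simulate_ld_blocks()] (variant metadata is generated from the block
#'   layout and `variants` is ignored) and `beta_exposure` must supply one
#'   entry per variant across all blocks.
#' @param seed Master integer seed.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_samples = 5902,
                       variants = default_hcy_variants(),
                       beta_exposure = NULL,
                       theta = 0.7,
                       alpha_pleiotropy = 0,
                       confounder_exposure = 0.15,
                       confounder_outcome = 0.25,
                       exposure_intercept = 2.45,
                       exposure_noise_sd = 0.2,
                       age_effect = 0.004,
                       sex_effect = 0.12,
                       component_prevalence =
                         c(0.30, 0.35, 0.45, 0.40, 0.33),
                       missing_rate = 0.002,
                       ld_blocks = NULL,
                       seed = 1L) {
  if (!is.null(ld_blocks)) {
    ld_blocks <- as_tibble(ld_blocks)
    assert_cols(ld_blocks, c("size", "freq", "r2"), "ld_blocks")
    variants <- dplyr::bind_rows(purrr::map(seq_len(nrow(ld_blocks)),
      function(b) tibble(
        snp_id = paste0("b", b, "_s", seq_len(ld_blocks$size[b])),
        effect_allele = "A", other_allele = "G",
        freq = ld_blocks$freq[b], block = b,
        is_index = seq_len(ld_blocks$size[b]) == 1L)))
  }
  variants <- as_tibble(variants)
  assert_cols(variants, c("snp_id", "effect_allele", "other_allele", "freq"),
              "variants")
  beta_exposure <- beta_exposure %||% variants$beta
  if (is.null(beta_exposure)) {
    abort("supply `beta_exposure` or a `beta` column in `variants`",
          class = "hcymr_validation_error")
  }
  k <- nrow(variants)
  if (length(beta_exposure) != k) {
    abort("`beta_exposure` must have one entry per variant",
          class = "hcymr_validation_error")
  }
  if (length(alpha_pleiotropy) == 1L) {
    alpha_pleiotropy <- rep(alpha_pleiotropy, k)
  }
  if (length(alpha_pleiotropy) != k) {
    abort("`alpha_pleiotropy` must be scalar or one per variant",
          class = "hcymr_validation_error")
  }
  if (anyDuplicated(variants$snp_id)) {
    abort("variant ids must be distinct", class = "hcymr_validation_error")
  }
  if (any(variants$effect_allele == variants$other_allele)) {
    abort("effect_allele must differ from other_allele",
          class = "hcymr_validation_error")
  }
  assert_prob(variants$freq, "variants$freq",
              open_left = TRUE, open_right = TRUE)
  assert_prob(missing_rate, "missing_rate", open_right = TRUE)
  assert_prob(component_prevalence, "component_prevalence",
              open_left = TRUE, open_right = TRUE)
  if (length(component_prevalence) != 5L) {
    abort("`component_prevalence` needs exactly 5 entries",
          class = "hcymr_validation_error")
  }
  if (!is.numeric(exposure_noise_sd) || exposure_noise_sd < 0 ||
      !is.finite(exposure_noise_sd)) {
    abort("`exposure_noise_sd` must be a nonnegative finite number",
          class = "hcymr_validation_error")
  }
  if (exposure_noise_sd == 0 && all(beta_exposure == 0)) {
    warn("zero-variance exposure requested: exposure_noise_sd = 0 and all beta_exposure = 0")
  }
  structure(list(
    n_samples = assert_count(n_samples, "n_samples"),
    variants = variants,
    beta_exposure = as.numeric(beta_exposure),
    theta = theta,
    alpha_pleiotropy = as.numeric(alpha_pleiotropy),
    confounder_exposure = confounder_exposure,
    confounder_outcome = confounder_outcome,
    exposure_intercept = exposure_intercept,
    exposure_noise_sd = exposure_noise_sd,
    age_effect = age_effect,
    sex_effect = sex_effect,
    component_prevalence = component_prevalence,
    missing_rate = missing_rate,
    ld_blocks = ld_blocks,
    seed = assert_count(seed, "seed", min = 0L)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config: n = %d, %d variants, theta = %.3g, seed = %d>\n",
    x$n_samples, nrow(x$variants), x$theta, x$seed))
  invisible(x)
}

#' Simulate Hardy-Weinberg genotypes
#'
#' Dosages are drawn per variant as Binomial(2, f) on the effect allele,
#' which yields Hardy-Weinberg genotype proportions
#' ((1-f)^2, 2f(1-f), f^2). Entries are then set missing independently with
#' probability `missing_rate`.
#'
#' @param freqs Effect-allele frequencies, each strictly in (0,1).
#' @param n Number of samples.
#' @param missing_rate Probability in [0,1) of a missing entry.
#' @param seed Integer seed; output is bit-identical for a fixed seed.
#' @param variants Optional variant metadata tibble; synthesized
#'   (`snp1...`, alleles A/B) when absent.
#' @return A [geno_tbl()].
#' @examples
#' g <- simulate_genotypes(c(0.3, 0.5), n = 100, seed = 7)
#' colMeans(geno_dosage(g)) / 2  # close to the allele frequencies
#' @export
simulate_genotypes <- function(freqs, n, missing_rate = 0, seed = 1L,
                               variants = NULL) {
  if (!is.numeric(freqs) || !length(freqs) || !all(is.finite(freqs)) ||
      any(freqs <= 0) || any(freqs >= 1)) {
    abort("allele frequencies must be finite and strictly inside (0,1)",
          class = "hcymr_validation_error")
  }
  n <- assert_count(n, "n")
  assert_prob(missing_rate, "missing_rate", open_right = TRUE)
  if (is.null(variants)) {
    variants <- tibble(
      snp_id = paste0("snp", seq_along(freqs)),
      effect_allele = "A", other_allele = "B", freq = freqs
    )
  }
  dosage <- with_local_seed(seed, {
    m <- vapply(freqs, function(f) rbinom(n, 2L, f), numeric(n))
    m <- matrix(m, nrow = n)
    if (missing_rate > 0) {
      m[runif(length(m)) < missing_rate] <- NA_real_
    }
    m
  })
  geno_tbl(dosage, variants)
}

#' Simulate genotypes in correlated LD blocks
#'
#' Generates blocks of variants with controlled pairwise linkage
#' disequilibrium, for exercising LD clumping. Within a block all variants
#' share the allele frequency of the first (index) variant; each tag
#' haplotype copies the index haplotype's allele with probability
#' `sqrt(r2)` and otherwise draws a fresh Bernoulli(f) allele, giving
#' pairwise allelic correlation `sqrt(r2)` and dosage r-squared close to
#' `r2`. Blocks are mutually independent. This is a pairwise-correlation
#' device, not a haplotype/coalescent model.
#'
#' @param blocks Tibble with one row per block: `size` (variants in the
#'   block), `freq` (index-variant allele frequency), `r2` (target
#'   within-block dosage r-squared).
#' @param n Number of samples.
#' @param missing_rate Per-entry missing probability.
#' @param seed Integer seed.
#' @return A [geno_tbl()] whose variant metadata carries `block` and
#'   `is_index` columns; ids are `b<block>_s<j>`.
#' @examples
#' g <- simulate_ld_blocks(
#'   tibble::tibble(size = c(3, 2), freq = c(0.3, 0.5), r2 = 0.9),
#'   n = 500, seed = 5)
#' ld_r2(geno_dosage(g)[, "b1_s1"], geno_dosage(g)[, "b1_s2"])
#' @export
simulate_ld_blocks <- function(blocks, n, missing_rate = 0, seed = 1L) {
  blocks <- as_tibble(blocks)
  assert_cols(blocks, c("size", "freq", "r2"), "blocks")
  assert_prob(blocks$freq, "blocks$freq", open_left = TRUE,
              open_right = TRUE)
  assert_prob(blocks$r2, "blocks$r2")
  n <- assert_count(n, "n")
  dosage <- with_local_seed(seed, {
    cols <- list()
    for (b in seq_len(nrow(blocks))) {
      m <- blocks$size[b]
      f <- blocks$freq[b]
      cc <- sqrt(blocks$r2[b])
      h1 <- rbinom(n, 1L, f)  # index haplotypes
      h2 <- rbinom(n, 1L, f)
      cols[[length(cols) + 1L]] <- h1 + h2
      if (m > 1) {
        for (j in seq_len(m - 1L)) {
          t1 <- ifelse(runif(n) < cc, h1, rbinom(n, 1L, f))
          t2 <- ifelse(runif(n) < cc, h2, rbinom(n, 1L, f))
          cols[[length(cols) + 1L]] <- t1 + t2
        }
      }
    }
    mat <- do.call(cbind, cols) * 1.0
    if (missing_rate > 0) {
      mat[runif(length(mat)) < missing_rate] <- NA_real_
    }
    mat
  })
  variants <- dplyr::bind_rows(purrr::map(seq_len(nrow(blocks)),
    function(b) {
      tibble(snp_id = paste0("b", b, "_s", seq_len(blocks$size[b])),
             effect_allele = "A", other_allele = "G",
             freq = blocks$freq[b], block = b,
             is_index = seq_len(blocks$size[b]) == 1L)
    }))
  geno_tbl(dosage, variants)
}

# ---- liability calibration --------------------------------------------------
#
# The five MetS components are Bernoulli draws from logistic liabilities that
# share a common slope `lambda` on standardized log-Hcy. MetS = (>=3 of 5), a
# nonlinear threshold, so lambda is NOT theta/5: we solve numerically for the
# lambda at which the marginal log-odds of MetS per 1 SD *genetic* shift in
# log-Hcy equals theta, integrating over the confounder U and the residual
# (non-U) exposure variation on an equal-probability quadrature grid.

# P(sum of 5 independent Bernoulli(p_k) >= 3), columns of `p` = components
poisbinom_ge3 <- function(p) {
  n <- nrow(p)
  dist <- matrix(0, n, 6L)
  dist[, 1L] <- 1
  for (k in seq_len(ncol(p))) {
    pk <- p[, k]
    nxt <- matrix(0, n, 6L)
    for (j in seq_len(k)) {
      nxt[, j] <- nxt[, j] + dist[, j] * (1 - pk)
      nxt[, j + 1L] <- nxt[, j + 1L] + dist[, j] * pk
    }
    dist <- nxt
  }
  rowSums(dist[, 4L:6L, drop = FALSE])
}

calibrate_liability <- function(theta, prevalence, c_x, c_y, tau, s,
                                m = 40L) {
  q <- qnorm((seq_len(m) - 0.5) / m)
  u <- rep(q, each = m)
  xi <- rep(q, times = m)
  z <- (c_x * u + tau * xi) / s

  comp_p <- function(lambda, a_k, mu = 0) {
    plogis(a_k + lambda * (z + mu) + c_y * u)
  }
  mets_prob <- function(lambda, a, mu = 0) {
    p <- vapply(a, function(a_k) comp_p(lambda, a_k, mu),
                numeric(length(z)))
    mean(poisbinom_ge3(p))
  }
  slope <- function(lambda, a, h = 0.1) {
    (qlogis(mets_prob(lambda, a, h)) - qlogis(mets_prob(lambda, a, -h))) /
      (2 * h)
  }
  solve_a <- function(lambda) {
    vapply(prevalence, function(target) {
      uniroot(function(a_k) mean(comp_p(lambda, a_k)) - target,
              c(-25, 25), tol = 1e-9)$root
    }, numeric(1))
  }

  a <- qlogis(prevalence)
  lambda <- 0
  if (theta == 0) {
    a <- solve_a(0)
  } else {
    for (iter in 1:3) {
      a <- solve_a(lambda)
      lambda <- uniroot(function(l) slope(l, a) - theta,
                        c(-60, 60), tol = 1e-8, extendInt = "upX")$root
    }
    a <- solve_a(lambda)
  }
  list(lambda = lambda, intercepts = a,
       mets_prevalence = mets_prob(lambda, a))
}

#' Simulate a full synthetic cohort
#'
#' Draws genotypes, covariates and the latent confounder, generates
#' log-homocysteine additively, generates the five MetS component flags from
#' calibrated logistic liabilities and scores MetS as three-or-more of five.
#' The generative model is
#' \deqn{\log Hcy = b_0 + \sum_i \beta_i g_i + c_X U + a(age-58) + s\,male + \epsilon}
#' with \eqn{\epsilon \sim N(0, \sigma^2)}, and each component
#' \eqn{C_k \sim Bernoulli(logit^{-1}(a_k + \lambda Z + c_Y U + \sum_i \alpha_i g_i))}
#' where \eqn{Z} is cohort-standardized log-Hcy and \eqn{\lambda} is
#' calibrated so that `theta` is the marginal MetS log-odds per 1 SD
#' genetically shifted log-Hcy. Missing dosages are mean-imputed inside
#' generative sums.
#'
#' @param config A [sim_config()].
#' @return A list with elements `genotypes` (a [geno_tbl()]), `phenotypes`
#'   (tibble with log_hcy, covariates, the five component flags,
#'   `mets_score`, `mets`, and the latent confounder `u` retained for
#'   validation) and `calibration` (the solved liability slope and
#'   intercepts).
#' @examples
#' cohort <- simulate_cohort(sim_config(n_samples = 500, seed = 42))
#' table(cohort$phenotypes$mets)
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) {
    abort("`config` must be created by sim_config()",
          class = "hcymr_validation_error")
  }
  cfg <- config
  n <- cfg$n_samples
  g <- if (is.null(cfg$ld_blocks)) {
    simulate_genotypes(cfg$variants$freq, n, cfg$missing_rate,
                       seed = derive_seed(cfg$seed, "genotypes"),
                       variants = cfg$variants)
  } else {
    simulate_ld_blocks(cfg$ld_blocks, n, cfg$missing_rate,
                       seed = derive_seed(cfg$seed, "genotypes"))
  }
  dos <- impute_dosage(geno_dosage(g))

  pheno <- with_local_seed(derive_seed(cfg$seed, "phenotypes"), {
    age <- round(pmin(pmax(rnorm(n, 58, 9), 40), 90))
    sex <- ifelse(runif(n) < 0.47, "M", "F")
    area <- ifelse(runif(n) < 0.513, "urban", "rural")
    smoking <- as.integer(runif(n) < ifelse(sex == "M", 0.28, 0.04))
    drinking <- as.integer(runif(n) < ifelse(sex == "M", 0.66, 0.24))
    rfs <- round(pmin(pmax(rnorm(n, 19, 8), 0), 49))
    bmi <- round(rnorm(n, 24.4, 3.1), 1)
    u <- rnorm(n)
    eps <- rnorm(n, 0, cfg$exposure_noise_sd)

    gscore <- drop(dos %*% cfg$beta_exposure)
    log_hcy <- cfg$exposure_intercept +
      cfg$age_effect * (age - 58) + cfg$sex_effect * (sex == "M") +
      gscore + cfg$confounder_exposure * u + eps

    s <- sd(log_hcy)
    if (!is.finite(s) || s == 0) s <- 1
    z <- (log_hcy - mean(log_hcy)) / s
    # residual (non-confounder) exposure SD for the calibration integral
    tau <- sqrt(max(s^2 - cfg$confounder_exposure^2, 1e-4))
    cal <- calibrate_liability(cfg$theta, cfg$component_prevalence,
                               cfg$confounder_exposure,
                               cfg$confounder_outcome, tau, s)
    pleio <- drop(dos %*% cfg$alpha_pleiotropy)
    comp <- vapply(seq_len(5L), function(k) {
      pr <- plogis(cal$intercepts[k] + cal$lambda * z +
                     cfg$confounder_outcome * u + pleio)
      rbinom(n, 1L, pr)
    }, integer(n))
    colnames(comp) <- c("comp_obesity", "comp_tg", "comp_hdl",
                        "comp_bp", "comp_glucose")
    sc <- mets_score(comp)
    list(tbl = dplyr::bind_cols(
      tibble(sample_id = g$sample_id, log_hcy = log_hcy, age = age,
             sex = sex, area = area, smoking = smoking,
             drinking = drinking, rfs = rfs, bmi = bmi),
      as_tibble(comp), sc, tibble(u = u)
    ), cal = cal)
  })

  list(genotypes = g, phenotypes = pheno$tbl, calibration = pheno$cal)
}

#' Score metabolic syndrome from its five components
#'
#' The MetS score is the number of components above their cut-offs (0-5);
#' MetS is present when three or more of the five components are.
#'
#' @param components A length-5 0/1 vector, or a matrix/data frame with 5
#'   binary columns (one row per sample).
#' @return A tibble with integer `mets_score` (0-5) and logical-as-integer
#'   `mets`.
#' @examples
#' mets_score(c(1, 1, 1, 0, 0))  # score 3 -> MetS
#' @export
mets_score <- function(components) {
  if (is.vector(components) && !is.list(components)) {
    components <- matrix(components, nrow = 1L)
  }
  m <- as.matrix(components)
  if (ncol(m) != 5L) {
    abort("exactly 5 component flags are required",
          class = "hcymr_validation_error")
  }
  if (anyNA(m)) {
    abort("missing component flag: impute or drop before scoring",
          class = "hcymr_validation_error")
  }
  if (!all(m %in% c(0, 1))) {
    abort("component flags must be 0/1", class = "hcymr_validation_error")
  }
  score <- as.integer(rowSums(m))
  tibble(mets_score = score, mets = as.integer(score >= 3L))
}

#' Derive MetS component flags from measured traits
#'
#' Applies the modified NCEP-ATP III criteria with Korean waist cut-offs:
#' central obesity is waist >= 90 cm (men) / >= 85 cm (women); high blood
#' pressure is systolic >= 130 or diastolic >= 85 mmHg or antihypertensive
#' treatment; triglycerides >= 150 mg/dL; HDL < 40 (men) / < 50 (women)
#' mg/dL; fasting glucose >= 100 mg/dL. All cut-offs are inclusive on the
#' `>=` side and configurable.
#'
#' @param data Data frame with columns `waist_cm`, `sex` ("M"/"F"), `tg`,
#'   `hdl`, `sbp`, `dbp`, `glucose`, `bp_treated` (0/1 or logical).
#' @param cutoffs Named list overriding any of `waist_m`, `waist_f`, `tg`,
#'   `hdl_m`, `hdl_f`, `sbp`, `dbp`, `glucose`.
#' @return Tibble with the five 0/1 component columns (`comp_obesity`,
#'   `comp_tg`, `comp_hdl`, `comp_bp`, `comp_glucose`).
#' @examples
#' derive_components(tibble::tibble(
#'   waist_cm = 90, sex = "M", tg = 120, hdl = 55, sbp = 129, dbp = 84,
#'   glucose = 95, bp_treated = TRUE))
#' @export
derive_components <- function(data, cutoffs = list()) {
  need <- c("waist_cm", "sex", "tg", "hdl", "sbp", "dbp", "glucose",
            "bp_treated")
  assert_cols(data, need, "data")
  cut <- utils::modifyList(list(
    waist_m = 90, waist_f = 85, tg = 150, hdl_m = 40, hdl_f = 50,
    sbp = 130, dbp = 85, glucose = 100
  ), cutoffs)
  num <- c("waist_cm", "tg", "hdl", "sbp", "dbp", "glucose")
  vals <- as.matrix(data[num])
  if (!all(is.finite(vals))) {
    abort("physiological measurements must be finite",
          class = "hcymr_validation_error")
  }
  if (any(vals < 0)) {
    abort("negative physiological values are invalid",
          class = "hcymr_validation_error")
  }
  if (!all(data$sex %in% c("M", "F"))) {
    abort("`sex` must be 'M' or 'F'", class = "hcymr_validation_error")
  }
  male <- data$sex == "M"
  tibble(
    comp_obesity = as.integer(
      data$waist_cm >= ifelse(male, cut$waist_m, cut$waist_f)),
    comp_tg = as.integer(data$tg >= cut$tg),
    comp_hdl = as.integer(data$hdl < ifelse(male, cut$hdl_m, cut$hdl_f)),
    comp_bp = as.integer(data$sbp >= cut$sbp | data$dbp >= cut$dbp |
                           as.logical(data$bp_treated)),
    comp_glucose = as.integer(data$glucose >= cut$glucose)
  )
}
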