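#' Select genome-wide significant instruments
#'
#' Keeps variants whose exposure association p-value is strictly below the
#' threshold (default 4e-8, a Bonferroni correction for an array of roughly
#' 1.25 million tests), sorted by ascending p with ties broken
#' lexicographically by id. A variant with p exactly equal to the threshold
#' is not selected.
#'
#' @param stats Summary-statistics tibble (exposure trait).
#' @param p_threshold Strict upper bound on p.
#' @return The selected rows, sorted; zero rows (with a warning) when
#'   nothing passes.
#' @export
select_instruments <- function(stats, p_threshold = 4e-8) {
  assert_cols(stats, c("snp_id", "p"), "stats")
  out <- stats |>
    dplyr::filter(.data$p < p_threshold) |>
    dplyr::arrange(.data$p, .data$snp_id)
  if (!nrow(out)) {
    warn(sprintf("no variants pass p < %g", p_threshold))
  }
  out
}

#' Squared Pearson correlation between two dosage vectors
#'
#' The LD measure used for clumping: r^2 over pairwise-complete samples.
#' A monomorphic vector has no LD information; r^2 is defined as 0 and
#' flagged with attribute `monomorphic = TRUE`.
#'
#' @param dosage_a,dosage_b Numeric dosage vectors (NA allowed).
#' @return r^2 in [0, 1].
#' @export
ld_r2 <- function(dosage_a, dosage_b) {
  ok <- !is.na(dosage_a) & !is.na(dosage_b)
  if (sum(ok) < 2L) {
    abort("need at least 2 pairwise-complete samples",
          class = "hcymr_validation_error")
  }
  a <- dosage_a[ok]
  b <- dosage_b[ok]
  if (var(a) == 0 || var(b) == 0) {
    return(structure(0, monomorphic = TRUE))
  }
  unname(cor(a, b)^2)
}

#' Greedy LD clumping
#'
#' Iterates variants by ascending p-value (ties broken by id) and retains a
#' variant iff its r^2 with every already-retained variant is below the
#' threshold; each removed variant records the retained index variant it
#' clumped to. The default threshold is r^2 < 0.01; the looser 0.1
#' convention can be requested via `r2_threshold`.
#'
#' @param stats Summary-statistics tibble with `snp_id` and `p`.
#' @param ref A [geno_tbl()] supplying the LD reference dosages; every
#'   `stats` variant must be present.
#' @param r2_threshold Exclusive upper bound on pairwise r^2 among retained
#'   variants.
#' @return A `clump_result` list: `retained` (ids), `removed` (tibble with
#'   `snp_id`, `index_snp`, `r2`), `threshold`.
#' @export
ld_clump <- function(stats, ref, r2_threshold = 0.01) {
  assert_cols(stats, c("snp_id", "p"), "stats")
  if (!is.numeric(r2_threshold) || r2_threshold <= 0 || r2_threshold > 1) {
    abort("`r2_threshold` must be in (0, 1]",
          class = "hcymr_validation_error")
  }
  dos <- geno_dosage(ref)
  absent <- setdiff(stats$snp_id, colnames(dos))
  if (length(absent)) {
    abort(paste0("variant(s) absent from LD reference: ",
                 paste(absent, collapse = ", ")),
          class = "hcymr_validation_error")
  }
  ord <- stats |>
    dplyr::arrange(.data$p, .data$snp_id)
  retained <- character()
  removed <- list()
  for (id in ord$snp_id) {
    r2s <- vapply(retained, function(r) as.numeric(ld_r2(dos[, id], dos[, r])),
                  numeric(1))
    hit <- which(r2s >= r2_threshold)
    if (length(hit)) {
      j <- hit[which.max(r2s[hit])]
      removed[[id]] <- tibble(snp_id = id, index_snp = retained[j],
                              r2 = unname(r2s[j]))
    } else {
      retained <- c(retained, id)
    }
  }
  structure(list(
    retained = retained,
    removed = if (length(removed)) dplyr::bind_rows(removed) else
      tibble(snp_id = character(), index_snp = character(),
             r2 = numeric()),
    threshold = r2_threshold
  ), class = "clump_result")
}

#' @export
print.clump_result <- function(x, ...) {
  cat(sprintf("<clump_result: %d retained, %d removed at r2 >= %g>\n",
              length(x$retained), nrow(x$removed), x$threshold))
  invisible(x)
}

#' First-stage instrument-strength F-statistic
#'
#' From the regression of the exposure on the k instruments (plus optional
#' covariates), F = (R2_inc / (1 - R2_full)) * (n - k - c - 1) / k, where
#' R2_inc is the instruments' incremental R-squared beyond the covariates
#' and c the number of covariate design columns (excluding the intercept).
#' With a single instrument and no covariates this equals the squared
#' first-stage t-statistic. A perfect fit returns `Inf` with attribute
#' `degenerate = TRUE`. The conventional weak-instrument rule of thumb is
#' F < 10.
#'
#' @param exposure Numeric exposure vector.
#' @param iv Instrument matrix/data frame/vector (dosages or a risk score).
#' @param covariates Optional covariate data frame.
#' @return One-row tibble: `f`, `r2` (incremental), `r2_full`, `k`, `n`,
#'   `df2`.
#' @export
f_statistic <- function(exposure, iv, covariates = NULL) {
  iv <- as.matrix(iv)
  n <- length(exposure)
  if (nrow(iv) != n) {
    abort("`iv` must have one row per sample",
          class = "hcymr_validation_error")
  }
  ok <- is.finite(exposure) & complete.cases(iv)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    ok <- ok & complete.cases(covariates)
  }
  y <- exposure[ok]
  iv <- iv[ok, , drop = FALSE]
  base <- build_design(if (is.null(covariates)) NULL else
    covariates[ok, , drop = FALSE], sum(ok))
  full <- cbind(base, iv)
  if (qr(full)$rank < ncol(full)) {
    abort("instrument design is rank deficient",
          class = "hcymr_rank_error")
  }
  k <- ncol(iv)
  cc <- ncol(base) - 1L
  n_ok <- length(y)
  if (n_ok <= k + cc + 1L) {
    abort("need n > k + covariates + 1", class = "hcymr_validation_error")
  }
  tss <- sum((y - mean(y))^2)
  rss_base <- sum(lm.fit(base, y)$residuals^2)
  rss_full <- sum(lm.fit(full, y)$residuals^2)
  r2_full <- 1 - rss_full / tss
  r2_base <- 1 - rss_base / tss
  r2_inc <- r2_full - r2_base
  df2 <- n_ok - k - cc - 1L
  if (rss_full <= .Machine$double.eps * tss) {
    return(structure(
      tibble(f = Inf, r2 = r2_inc, r2_full = r2_full, k = k, n = n_ok,
             df2 = df2),
      degenerate = TRUE))
  }
  tibble(f = (r2_inc / (1 - r2_full)) * df2 / k,
         r2 = r2_inc, r2_full = r2_full, k = k, n = n_ok, df2 = df2)
}

#' Screen instruments for confounder associations
#'
#' Regresses each candidate confounder on each variant's dosage (additive
#' coding), adjusted for age, sex and area: linear regression for
#' continuous confounders (e.g. RFS, BMI), logistic for binary ones
#' (smoking, drinking). An instrument associated with a confounder
#' violates the exchangeability assumption; rows with p below `flag_alpha`
#' are flagged.
#'
#' @param g A [geno_tbl()].
#' @param pheno Phenotype tibble holding confounders and adjustment
#'   covariates.
#' @param confounders Named character vector mapping confounder column ->
#'   `"linear"` or `"logistic"`.
#' @param adjust Adjustment covariate columns (default age, sex, area).
#' @param flag_alpha Flagging threshold.
#' @return Tibble: `snp_id`, `confounder`, `model`, `beta`, `se`, `p`,
#'   `n`, `flagged`.
#' @export
confounder_screen <- function(g, pheno,
                              confounders = c(smoking = "logistic",
                                              drinking = "logistic",
                                              rfs = "linear",
                                              bmi = "linear"),
                              adjust = c("age", "sex", "area"),
                              flag_alpha = 0.05) {
  assert_cols(pheno, c(names(confounders), adjust), "pheno")
  covs <- if (length(adjust)) pheno[adjust] else NULL
  purrr::imap(as.list(confounders), function(type, cname) {
    y <- pheno[[cname]]
    res <- if (type == "linear") {
      linear_assoc(g, as.numeric(y), covariates = covs,
                   trait = paste0("confounder:", cname))
    } else {
      logistic_assoc(g, as.integer(y), covariates = covs,
                     trait = paste0("confounder:", cname))
    }
    dplyr::mutate(res, confounder = cname)
  }) |>
    dplyr::bind_rows() |>
    dplyr::mutate(flagged = .data$p < flag_alpha) |>
    dplyr::select("snp_id", "confounder", "model", "beta", "se", "p",
                  "n", "flagged")
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns outcome effects to the exposure's effect allele for every shared
#' variant: matching alleles are copied; swapped alleles flip the sign of
#' the outcome beta; irreconcilable allele pairs are dropped with a report
#' entry. A/T and G/C variants are flagged palindromic and dropped when
#' their minor-allele frequency exceeds `drop_palindromic_maf` (strand
#' unresolvable from frequency); palindromic variants without frequency
#' information are kept but flagged. Finally each instrument is oriented to
#' the exposure-increasing allele (beta_x >= 0, flipping both betas
#' together), the orientation MR-Egger requires.
#'
#' @param exposure,outcome Summary-statistics tibbles with `snp_id`,
#'   `effect_allele`, `other_allele`, `beta`, `se` (and optionally `eaf`).
#' @param drop_palindromic_maf MAF above which a palindromic variant is
#'   dropped (default 0.42).
#' @return An `mr_instruments` tibble: `snp_id`, post-orientation alleles,
#'   `beta_x`, `se_x`, `beta_y`, `se_y`, `orientation_flipped`,
#'   `palindromic`; dropped variants in attribute `"dropped"`.
#' @export
harmonize <- function(exposure, outcome, drop_palindromic_maf = 0.42) {
  for (nm in c("exposure", "outcome")) {
    assert_cols(get(nm), c("snp_id", "effect_allele", "other_allele",
                           "beta", "se"), nm)
  }
  shared <- intersect(exposure$snp_id, outcome$snp_id)
  if (!length(shared)) {
    abort("no shared variants between exposure and outcome",
          class = "hcymr_empty_error")
  }
  ex <- exposure[match(shared, exposure$snp_id), ]
  ou <- outcome[match(shared, outcome$snp_id), ]
  eaf <- if ("eaf" %in% names(ex)) ex$eaf else rep(NA_real_, nrow(ex))

  same <- ou$effect_allele == ex$effect_allele &
    ou$other_allele == ex$other_allele
  swapped <- ou$effect_allele == ex$other_allele &
    ou$other_allele == ex$effect_allele
  pal <- paste0(ex$effect_allele, ex$other_allele) %in%
    c("AT", "TA", "CG", "GC")
  maf <- pmin(eaf, 1 - eaf)
  drop_pal <- pal & !is.na(maf) & maf > drop_palindromic_maf
  bad <- !(same | swapped)

  dropped <- dplyr::bind_rows(
    tibble(snp_id = shared[bad], reason = "allele_mismatch"),
    tibble(snp_id = shared[!bad & drop_pal],
           reason = "palindromic_high_maf")
  )
  keep <- !bad & !drop_pal
  beta_y <- ifelse(swapped, -ou$beta, ou$beta)

  out <- tibble(
    snp_id = shared, effect_allele = ex$effect_allele,
    other_allele = ex$other_allele, eaf = eaf,
    beta_x = ex$beta, se_x = ex$se, beta_y = beta_y, se_y = ou$se,
    orientation_flipped = FALSE, palindromic = pal
  )[keep, ]

  flip <- out$beta_x < 0
  out$beta_y[flip] <- -out$beta_y[flip]
  out$beta_x[flip] <- -out$beta_x[flip]
  out$eaf[flip] <- 1 - out$eaf[flip]
  ea <- out$effect_allele
  out$effect_allele[flip] <- out$other_allele[flip]
  out$other_allele[flip] <- ea[flip]
  out$orientation_flipped <- flip

  if (!nrow(out)) {
    abort("no harmonizable variants remain", class = "hcymr_empty_error")
  }
  structure(out, dropped = dropped,
            class = c("mr_instruments", class(tibble())))
}

#' Reconstruct log-odds summary statistics from an OR and 95% CI
#'
#' The ingestion rule for published per-variant odds ratios:
#' beta = ln(OR) and se = (ln(hi) - ln(lo)) / (2 * 1.959964).
#'
#' @param or Odds ratio(s).
#' @param ci_low,ci_high 95% confidence bounds.
#' @return Tibble with `beta` and `se`.
#' @export
or_to_beta <- function(or, ci_low, ci_high) {
  tibble(beta = log(or),
         se = (log(ci_high) - log(ci_low)) / (2 * 1.959964))
}
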