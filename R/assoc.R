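#' Hardy-Weinberg equilibrium test
#'
#' Tests observed genotype counts (hom-ref, het, hom-alt) against the
#' Hardy-Weinberg expectation ((1-f)^2, 2f(1-f), f^2) with the allele
#' frequency estimated from the counts. The default is the conventional
#' 1-df chi-square goodness-of-fit test used in array QC; an exact
#' (conditional, mid-p) test is available via `method = "exact"`.
#' Monomorphic count triples carry no HWE information: the p-value is
#' defined as 1 and flagged with attribute `monomorphic = TRUE`.
#'
#' @param counts Integer vector `(n_AA, n_Aa, n_aa)`, total > 0.
#' @param method `"chisq"` (default) or `"exact"` (mid-p).
#' @return The HWE p-value.
#' @examples
#' hwe_test(c(25, 50, 25))  # perfect HWE, p = 1
#' hwe_test(c(50, 0, 50))   # complete heterozygote deficit
#' @export
hwe_test <- function(counts, method = c("chisq", "exact")) {
  method <- match.arg(method)
  if (length(counts) != 3L || any(counts < 0) || anyNA(counts) ||
      any(counts != floor(counts))) {
    abort("`counts` must be 3 nonnegative integers (n_AA, n_Aa, n_aa)",
          class = "hcymr_validation_error")
  }
  n <- sum(counts)
  if (n == 0) {
    abort("total genotype count is zero", class = "hcymr_validation_error")
  }
  n_a <- 2 * counts[3L] + counts[2L]  # alt allele count
  if (n_a == 0 || n_a == 2 * n) {
    return(structure(1, monomorphic = TRUE))
  }
  if (method == "chisq") {
    f <- n_a / (2 * n)
    expected <- n * c((1 - f)^2, 2 * f * (1 - f), f^2)
    stat <- sum((counts - expected)^2 / expected)
    pchisq(stat, df = 1, lower.tail = FALSE)
  } else {
    hwe_exact_midp(counts)
  }
}

# Exact HWE test conditional on allele counts, mid-p version. Probabilities
# over the admissible heterozygote counts are built by the standard
# ratio recurrence to avoid factorial overflow.
hwe_exact_midp <- function(counts) {
  n <- sum(counts)
  rare <- min(2 * counts[3L] + counts[2L], 2 * counts[1L] + counts[2L])
  het_obs <- counts[2L]
  hets <- seq(rare %% 2, rare, by = 2)
  lp <- numeric(length(hets))
  for (i in seq_along(hets)[-1]) {
    h <- hets[i]
    # P(h)/P(h-2) = 4 * n_hom_rare(h-2) * n_hom_common(h-2) / (h * (h-1))
    hr <- (rare - (h - 2)) / 2
    hc <- n - (h - 2) - hr
    lp[i] <- lp[i - 1] + log(4 * hr * hc) - log(h * (h - 1))
  }
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  p_obs <- pr[match(het_obs, hets)]
  sum(pr[pr < p_obs]) + 0.5 * sum(pr[abs(pr - p_obs) < 1e-12])
}

#' Genotype quality-control filter
#'
#' Removes variants in a fixed order — (1) missing rate above
#' `max_missing`, (2) monomorphic among non-missing samples, (3)
#' Hardy-Weinberg p-value below `hwe_alpha` — so the report counts are
#' unambiguous. Defaults are the conventional array-QC thresholds
#' (missingness > 0.01, HWE p < 1e-6).
#'
#' @param g A [geno_tbl()].
#' @param max_missing Maximum tolerated per-variant missing rate.
#' @param hwe_alpha HWE p-value threshold (remove when p < alpha).
#' @param hwe_method Passed to [hwe_test()].
#' @return A list with `genotypes` (filtered [geno_tbl()]) and `report`
#'   (a `qc_report` with counts and per-variant removal reasons).
#' @export
qc_filter <- function(g, max_missing = 0.01, hwe_alpha = 1e-6,
                      hwe_method = "chisq") {
  assert_prob(max_missing, "max_missing")
  assert_prob(hwe_alpha, "hwe_alpha", open_left = TRUE)
  dos <- geno_dosage(g)
  if (!ncol(dos)) abort("empty genotype table", class = "hcymr_empty_error")
  ids <- colnames(dos)

  miss <- colMeans(is.na(dos))
  rm_miss <- ids[miss > max_missing]
  keep <- setdiff(ids, rm_miss)

  mono <- vapply(keep, function(id) {
    x <- dos[, id]
    length(unique(x[!is.na(x)])) <= 1L
  }, logical(1))
  rm_mono <- keep[mono]
  keep <- setdiff(keep, rm_mono)

  hwe_p <- vapply(keep, function(id) {
    x <- dos[, id]
    x <- x[!is.na(x)]
    as.numeric(hwe_test(c(sum(x == 0), sum(x == 1), sum(x == 2)),
                        method = hwe_method))
  }, numeric(1))
  rm_hwe <- keep[hwe_p < hwe_alpha]
  keep <- setdiff(keep, rm_hwe)

  if (!length(keep)) {
    abort("all variants removed by QC", class = "hcymr_empty_error")
  }
  removed <- dplyr::bind_rows(
    tibble(snp_id = rm_miss, reason = "missingness",
           value = miss[rm_miss]),
    tibble(snp_id = rm_mono, reason = "monomorphic", value = NA_real_),
    tibble(snp_id = rm_hwe, reason = "hwe",
           value = unname(hwe_p[rm_hwe]))
  )
  report <- structure(list(
    n_input = length(ids),
    n_removed_missingness = length(rm_miss),
    n_removed_monomorphic = length(rm_mono),
    n_removed_hwe = length(rm_hwe),
    retained = keep,
    removed = removed
  ), class = "qc_report")
  list(genotypes = geno_subset(g, keep), report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(
    "<qc_report: %d in, removed %d missingness / %d monomorphic / %d HWE, %d retained>\n",
    x$n_input, x$n_removed_missingness, x$n_removed_monomorphic,
    x$n_removed_hwe, length(x$retained)))
  invisible(x)
}

# ---- regression engines -----------------------------------------------------

# Build an intercept + covariate design matrix and fail loudly on rank
# deficiency, naming the offending columns.
build_design <- function(covariates, n) {
  if (is.null(covariates)) {
    return(matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)")))
  }
  covariates <- as.data.frame(covariates)
  x <- stats::model.matrix(~., data = covariates)
  qrx <- qr(x)
  if (qrx$rank < ncol(x)) {
    bad <- colnames(x)[qrx$pivot[(qrx$rank + 1):ncol(x)]]
    abort(paste0("covariate design is rank deficient; collinear column(s): ",
                 paste(bad, collapse = ", ")),
          class = "hcymr_rank_error")
  }
  x
}

fit_ols <- function(x, y) {
  fit <- lm.fit(x, y)
  df <- length(y) - fit$rank
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / df
  xtx_inv <- chol2inv(qr.R(fit$qr))
  se <- sqrt(diag(xtx_inv) * sigma2)
  list(coef = fit$coefficients, se = se, df = df, rss = rss,
       fitted = fit$fitted.values)
}

# Logistic regression by iteratively reweighted least squares (via
# stats::glm.fit). Convergence: relative deviance change < 1e-10 within 50
# iterations; complete separation is flagged by diverging coefficients
# (|beta| > 30) or boundary fitted probabilities.
fit_logistic <- function(x, y) {
  if (length(unique(y)) < 2L) {
    abort("outcome has a single class", class = "hcymr_separation_error")
  }
  fit <- suppressWarnings(
    glm.fit(x, y, family = binomial(),
            control = glm.control(epsilon = 1e-10, maxit = 50L))
  )
  if (!fit$converged) {
    abort("logistic regression did not converge within 50 IRLS iterations",
          class = "hcymr_convergence_error")
  }
  if (any(abs(fit$coefficients) > 30, na.rm = TRUE)) {
    abort(paste0("apparent complete separation (|beta| > 30) for: ",
                 paste(colnames(x)[abs(fit$coefficients) > 30],
                       collapse = ", ")),
          class = "hcymr_separation_error")
  }
  w <- fit$weights
  xtwx <- crossprod(x * sqrt(w))
  cov <- chol2inv(chol(xtwx))
  list(coef = fit$coefficients, se = sqrt(diag(cov)),
       fitted = fit$fitted.values, deviance = fit$deviance)
}

#' Per-variant association scans
#'
#' `linear_assoc()` regresses a continuous trait on each variant's dosage
#' plus covariates by ordinary least squares (two-sided p from the t
#' distribution); `logistic_assoc()` fits a per-variant logistic model by
#' iteratively reweighted least squares (Wald p from the standard normal).
#' Samples with a missing dosage are dropped per variant; rows with missing
#' trait or covariates are dropped listwise.
#'
#' @param g A [geno_tbl()].
#' @param y Continuous trait vector (`linear_assoc`) or 0/1 case vector
#'   (`logistic_assoc`), one per sample.
#' @param covariates Optional data frame of covariates (factors allowed).
#' @param trait Label stored in the output `trait` column.
#' @return A summary-statistics tibble with columns
#'   `snp_id, effect_allele, other_allele, beta, se, p, n, trait, model`.
#' @examples
#' g <- simulate_genotypes(c(0.4, 0.3), n = 300, seed = 3)
#' y <- 0.5 * geno_dosage(g)[, 1] + rnorm(300)
#' linear_assoc(g, y)
#' @export
linear_assoc <- function(g, y, covariates = NULL, trait = "exposure") {
  assoc_scan(g, y, covariates, trait, model = "linear")
}

#' @rdname linear_assoc
#' @export
logistic_assoc <- function(g, y, covariates = NULL, trait = "outcome") {
  assoc_scan(g, y, covariates, trait, model = "logistic")
}

assoc_scan <- function(g, y, covariates, trait, model) {
  v <- geno_variants(g)
  dos <- geno_dosage(g)
  if (length(y) != nrow(dos)) {
    abort("`y` must have one value per sample",
          class = "hcymr_validation_error")
  }
  base_ok <- !is.na(y)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    base_ok <- base_ok & complete.cases(covariates)
  }
  if (model == "linear" && !all(is.finite(y[base_ok]))) {
    abort("`y` must be finite", class = "hcymr_validation_error")
  }
  res <- purrr::map(v$snp_id, function(id) {
    ok <- base_ok & !is.na(dos[, id])
    x <- build_design(if (is.null(covariates)) NULL else
      covariates[ok, , drop = FALSE], sum(ok))
    x <- cbind(x, dosage = dos[ok, id])
    yk <- y[ok]
    if (model == "linear") {
      f <- fit_ols(x, yk)
      b <- f$coef[["dosage"]]
      se <- f$se[[length(f$se)]]
      p <- 2 * pt(abs(b / se), df = f$df, lower.tail = FALSE)
    } else {
      f <- fit_logistic(x, yk)
      b <- f$coef[["dosage"]]
      se <- f$se[[length(f$se)]]
      p <- 2 * pnorm(abs(b / se), lower.tail = FALSE)
    }
    tibble(snp_id = id, beta = unname(b), se = unname(se),
           p = unname(p), n = sum(ok))
  })
  dplyr::bind_rows(res) |>
    dplyr::left_join(v[, c("snp_id", "effect_allele", "other_allele")],
                     by = "snp_id") |>
    dplyr::mutate(trait = trait, model = model) |>
    dplyr::select("snp_id", "effect_allele", "other_allele", "beta",
                  "se", "p", "n", "trait", "model")
}

#' Observational homocysteine-MetS logistic regressions
#'
#' Fits logistic regressions of MetS on log-homocysteine across nested
#' covariate sets (the classical univariate / progressively adjusted
#' layout): none; age+sex+area; +smoking+drinking; +RFS+BMI. Odds ratios
#' carry 95% Wald confidence intervals. `scale` selects the exposure unit:
#' `"raw"` (per unit log-Hcy) or `"sd"` (per cohort SD of log-Hcy) — both
#' conventions appear in the epidemiological literature, so both are
#' exposed.
#'
#' @param pheno Phenotype tibble with `log_hcy`, `mets` and any covariates
#'   referenced by `covariate_sets`.
#' @param covariate_sets Named list of character vectors of covariate
#'   column names; default mirrors the standard nested adjustment sets.
#' @param scale `"raw"` or `"sd"`.
#' @return Tibble with one row per covariate set: `model`, `or`, `ci_low`,
#'   `ci_high`, `beta`, `se`, `p`, `n`, `covariates`.
#' @export
observational_or <- function(pheno,
                             covariate_sets = list(
                               univariate = character(),
                               multivariate1 = c("age", "sex", "area"),
                               multivariate2 = c("age", "sex", "area",
                                                 "smoking", "drinking"),
                               multivariate3 = c("age", "sex", "area",
                                                 "smoking", "drinking",
                                                 "rfs", "bmi")),
                             scale = c("raw", "sd")) {
  scale <- match.arg(scale)
  assert_cols(pheno, c("log_hcy", "mets"), "pheno")
  x_raw <- pheno$log_hcy
  x <- if (scale == "sd") (x_raw - mean(x_raw, na.rm = TRUE)) /
    sd(x_raw, na.rm = TRUE) else x_raw
  purrr::imap(covariate_sets, function(cols, label) {
    assert_cols(pheno, cols, "pheno")
    covs <- if (length(cols)) as.data.frame(pheno[cols]) else NULL
    ok <- !is.na(x) & !is.na(pheno$mets)
    if (!is.null(covs)) ok <- ok & complete.cases(covs)
    design <- build_design(if (is.null(covs)) NULL else
      covs[ok, , drop = FALSE], sum(ok))
    design <- cbind(design, hcy = x[ok])
    f <- fit_logistic(design, pheno$mets[ok])
    b <- unname(f$coef[["hcy"]])
    se <- unname(f$se[[length(f$se)]])
    tibble(model = label, or = exp(b),
           ci_low = exp(b - 1.959964 * se),
           ci_high = exp(b + 1.959964 * se),
           beta = b, se = se,
           p = 2 * pnorm(abs(b / se), lower.tail = FALSE),
           n = sum(ok), covariates = paste(cols, collapse = "+"))
  }) |>
    dplyr::bind_rows()
}

#' Descriptive statistics by exposure quartile
#'
#' Splits the cohort into quartiles of `log_hcy` at the empirical 25/50/75
#' percentiles (right-closed intervals: a value equal to a cut-point falls
#' in the lower quartile) and summarizes each variable per quartile.
#' Continuous variables are reported as mean (SD) and median (IQR) with
#' one-way ANOVA and Kruskal-Wallis p-values; binary/categorical variables
#' as percentages with a chi-square p-value.
#'
#' @param pheno Phenotype tibble.
#' @param exposure Column to form quartiles on (default `"log_hcy"`).
#' @param variables Columns to summarize; defaults to every column except
#'   identifiers and the exposure.
#' @return A long tibble: `variable`, `type`, `quartile`, `n`, `mean`,
#'   `sd`, `median`, `q1`, `q3`, `percent`, `anova_p`, `kruskal_p`,
#'   `chisq_p`.
#' @export
quartile_summary <- function(pheno, exposure = "log_hcy",
                             variables = NULL) {
  assert_cols(pheno, exposure, "pheno")
  x <- pheno[[exposure]]
  if (length(x) < 4L) {
    abort("need at least 4 samples to form quartiles",
          class = "hcymr_validation_error")
  }
  br <- quantile(x, c(0, 0.25, 0.5, 0.75, 1), na.rm = TRUE)
  if (anyDuplicated(br)) {
    abort("tied quartile cut-points leave empty quartiles; use fewer bins",
          class = "hcymr_validation_error")
  }
  q <- cut(x, breaks = br, include.lowest = TRUE,
           labels = c("Q1", "Q2", "Q3", "Q4"))
  variables <- variables %||%
    setdiff(names(pheno), c("sample_id", exposure))
  purrr::map(variables, function(vn) {
    v <- pheno[[vn]]
    if (is.numeric(v) && length(unique(v[!is.na(v)])) > 2L) {
      fit <- aov(v ~ q)
      an <- summary(fit)[[1]]
      pv <- an[["Pr(>F)"]]
      # saturated fits (no residual df) yield no p; identical group
      # means give F = 0 and hence p = 1 through the usual upper tail
      anova_p <- if (is.null(pv)) NA_real_ else pv[1]
      kw <- kruskal.test(v, q)$p.value
      dplyr::group_by(tibble(v = v, q = q), q) |>
        dplyr::summarise(
          n = dplyr::n(), mean = mean(v, na.rm = TRUE),
          sd = sd(v, na.rm = TRUE),
          median = median(v, na.rm = TRUE),
          q1 = quantile(v, 0.25, na.rm = TRUE),
          q3 = quantile(v, 0.75, na.rm = TRUE), .groups = "drop") |>
        dplyr::mutate(variable = vn, type = "continuous",
                      percent = NA_real_, anova_p = anova_p,
                      kruskal_p = kw, chisq_p = NA_real_) |>
        dplyr::rename(quartile = "q")
    } else {
      tab <- table(q, v)
      chi <- suppressWarnings(chisq.test(tab))$p.value
      lev <- colnames(tab)[ncol(tab)]  # report the highest level's share
      dplyr::group_by(tibble(v = as.character(v), q = q), q) |>
        dplyr::summarise(
          n = dplyr::n(), percent = 100 * mean(v == lev, na.rm = TRUE),
          .groups = "drop") |>
        dplyr::mutate(variable = vn, type = "categorical",
                      mean = NA_real_, sd = NA_real_, median = NA_real_,
                      q1 = NA_real_, q3 = NA_real_,
                      anova_p = NA_real_, kruskal_p = NA_real_,
                      chisq_p = chi) |>
        dplyr::rename(quartile = "q")
    }
  }) |>
    dplyr::bind_rows() |>
    dplyr::select("variable", "type", "quartile", "n", "mean", "sd",
                  "median", "q1", "q3", "percent", "anova_p",
                  "kruskal_p", "chisq_p")
}
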