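#' Wald-ratio causal estimate with delta-method standard error
#'
#' The single-instrument MR estimator: the causal log-odds per exposure
#' unit is the ratio of the per-allele outcome effect to the per-allele
#' exposure effect, estimate = beta_y / beta_x, with first-order
#' delta-method SE assuming independent numerator and denominator errors:
#' \deqn{se = \sqrt{se_y^2 / \beta_x^2 + \beta_y^2 se_x^2 / \beta_x^4}.}
#' An instrument with |beta_x| / se_x < 1 attaches a weak-instrument
#' warning.
#'
#' @param beta_x,se_x Per-allele effect on the exposure and its SE.
#' @param beta_y,se_y Per-allele effect on the outcome (log-odds) and SE.
#' @return An `mr_result` row (`method = "wald_ratio"`).
#' @examples
#' wald_ratio(beta_x = 0.039, se_x = 0.005, beta_y = 0.0523, se_y = 0.0561)
#' @export
wald_ratio <- function(beta_x, se_x, beta_y, se_y) {
  if (!is.finite(beta_x) || beta_x == 0) {
    abort("beta_x = 0: Wald ratio undefined", class = "hcymr_ratio_error")
  }
  if (se_x < 0 || se_y <= 0) {
    abort("standard errors must be positive (se_x may be 0 for a known instrument)",
          class = "hcymr_validation_error")
  }
  est <- beta_y / beta_x
  se <- sqrt(se_y^2 / beta_x^2 + beta_y^2 * se_x^2 / beta_x^4)
  out <- new_mr_result("wald_ratio", est, se,
                       p = 2 * pnorm(abs(est / se), lower.tail = FALSE),
                       k = 1L)
  if (se_x > 0 && abs(beta_x) / se_x < 1) {
    attr(out, "weak_instrument") <- TRUE
    warn("weak instrument: |beta_x| / se_x < 1", class = "hcymr_weak_iv")
  }
  out
}

#' Build a genetic risk score
#'
#' Sums exposure-increasing alleles, weighted by their effect sizes, under
#' an additive model (score = sum_i w_i * dosage_i) or a dominant model
#' (the per-variant dosage is replaced by a carrier indicator,
#' dosage >= 1). Weights must be oriented to the exposure-increasing
#' allele; a negative weight is taken to mean the effect allele is
#' exposure-decreasing, so that variant's dosage is flipped (2 - d) and the
#' weight negated. Missing dosages are mean-imputed.
#'
#' @param g A [geno_tbl()].
#' @param weights Named numeric vector or tibble (`snp_id`, `weight`);
#'   every name must be present in `g`.
#' @param model `"additive"` or `"dominant"`.
#' @return Tibble with `sample_id` and `grs`; the oriented weights and
#'   model are attached as attributes.
#' @export
build_grs <- function(g, weights, model = c("additive", "dominant")) {
  model <- match.arg(model)
  if (is.data.frame(weights)) {
    assert_cols(weights, c("snp_id", "weight"), "weights")
    weights <- setNames(weights$weight, weights$snp_id)
  }
  dos <- geno_dosage(g)
  absent <- setdiff(names(weights), colnames(dos))
  if (length(absent)) {
    abort(paste0("weight(s) for variant(s) absent from genotypes: ",
                 paste(absent, collapse = ", ")),
          class = "hcymr_validation_error")
  }
  dos <- impute_dosage(dos[, names(weights), drop = FALSE])
  neg <- weights < 0
  if (any(neg)) {
    dos[, neg] <- 2 - dos[, neg]
    weights[neg] <- -weights[neg]
  }
  if (model == "dominant") dos <- (dos >= 1) * 1
  score <- unname(drop(dos %*% weights))
  structure(tibble(sample_id = g$sample_id, grs = score),
            weights = weights, model = model)
}

#' Two-stage least squares with a logistic second stage
#'
#' One-sample MR for a binary outcome: stage 1 regresses the exposure on
#' the instrument(s) plus covariates by OLS; stage 2 regresses the outcome
#' on the stage-1 fitted exposure plus covariates by logistic regression.
#' The causal estimate is the stage-2 coefficient on the fitted exposure,
#' rescaled to log-odds per 1 SD of the observed exposure. This
#' two-stage predictor substitution is the standard field procedure for a
#' binary outcome; its estimate approximates, but is not exactly, the
#' marginal causal log-OR (see `se_method` note in the output and the
#' methods vignette). Naive stage-2 Wald SEs ignore first-stage
#' uncertainty; a nonparametric bootstrap over samples is available via
#' `boot > 0` (percentile CI).
#'
#' @param data Tibble holding all referenced columns.
#' @param exposure,outcome Column names of the continuous exposure and the
#'   0/1 outcome.
#' @param instruments Character vector of instrument columns (dosages or a
#'   GRS column).
#' @param covariates Optional character vector of covariate columns.
#' @param per_sd Rescale to per-SD-of-exposure units (default TRUE).
#' @param family `"logistic"` (binary outcome; default) or `"gaussian"`
#'   (continuous outcome, classical linear 2SLS second stage).
#' @param boot Number of bootstrap resamples (0 = naive Wald SE).
#' @param seed Seed for the bootstrap.
#' @return An `mr_result` row (`method = "tsls"`) with the first-stage F
#'   in `f_stat` and `se_method` noting which SE was used.
#' @export
tsls <- function(data, exposure, outcome, instruments,
                 covariates = NULL, per_sd = TRUE,
                 family = c("logistic", "gaussian"), boot = 0L,
                 seed = 1L) {
  family <- match.arg(family)
  assert_cols(data, c(exposure, outcome, instruments, covariates), "data")
  ok <- complete.cases(data[c(exposure, outcome, instruments, covariates)])
  data <- data[ok, ]
  x <- data[[exposure]]
  y <- data[[outcome]]
  iv <- as.matrix(data[instruments])
  covs <- if (length(covariates)) as.data.frame(data[covariates]) else NULL

  fstat <- f_statistic(x, iv, covs)
  if (is.finite(fstat$f) && fstat$f < 10) {
    warn(sprintf("weak instrument: first-stage F = %.2f < 10", fstat$f),
         class = "hcymr_weak_iv")
  }
  est_fun <- function(d) {
    xs <- d[[exposure]]
    ys <- d[[outcome]]
    ivs <- as.matrix(d[instruments])
    cvs <- if (length(covariates)) as.data.frame(d[covariates]) else NULL
    base <- build_design(cvs, nrow(d))
    s1 <- fit_ols(cbind(base, ivs), xs)
    design2 <- cbind(base, fitted_exposure = s1$fitted)
    s2 <- if (family == "logistic") fit_logistic(design2, ys) else
      fit_ols(design2, ys)
    b <- unname(s2$coef[["fitted_exposure"]])
    se <- unname(s2$se[[length(s2$se)]])
    scale <- if (per_sd) sd(xs) else 1
    c(b * scale, se * scale)
  }
  point <- est_fun(data)
  if (boot > 0) {
    boots <- with_local_seed(derive_seed(seed, "bootstrap"), {
      vapply(seq_len(boot), function(i) {
        idx <- sample.int(nrow(data), replace = TRUE)
        est_fun(data[idx, ])[1]
      }, numeric(1))
    })
    se <- sd(boots)
    ci <- unname(quantile(boots, c(0.025, 0.975)))
    out <- new_mr_result("tsls", point[1], se,
                         p = 2 * pnorm(abs(point[1] / se),
                                       lower.tail = FALSE),
                         k = length(instruments),
                         f_stat = fstat$f,
                         se_method = sprintf("bootstrap(%d)", boot))
    out$ci_low <- ci[1]
    out$ci_high <- ci[2]
    out
  } else {
    new_mr_result("tsls", point[1], point[2],
                  p = 2 * pnorm(abs(point[1] / point[2]),
                                lower.tail = FALSE),
                  k = length(instruments), f_stat = fstat$f,
                  se_method = "naive_wald (ignores first-stage uncertainty)")
  }
}
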