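# Two-sample MR estimators on harmonized instruments.
# All operate on a tibble with beta_x, se_x, beta_y, se_y (one row per
# instrument), as produced by harmonize().

check_instr <- function(instr, k_min = 1L, caller = "estimator") {
  assert_cols(instr, c("beta_x", "se_x", "beta_y", "se_y"), "instr")
  if (nrow(instr) < k_min) {
    abort(sprintf("%s requires at least %d instruments, got %d",
                  caller, k_min, nrow(instr)),
          class = "hcymr_validation_error")
  }
  if (any(instr$se_y <= 0) || any(instr$se_x < 0)) {
    abort("instrument standard errors must be positive",
          class = "hcymr_validation_error")
  }
  instr
}

# orient so beta_x >= 0, flipping beta_y with it (required by Egger, I2GX)
orient_instr <- function(instr) {
  flip <- instr$beta_x < 0
  instr$beta_y[flip] <- -instr$beta_y[flip]
  instr$beta_x[flip] <- -instr$beta_x[flip]
  instr
}

#' Fixed-effect inverse-variance meta-analysis of per-variant outcome
#' associations
#'
#' Pools each variant's outcome association across cohorts with
#' inverse-variance weights: beta = sum(b/s^2) / sum(1/s^2),
#' se = (sum 1/s^2)^(-1/2), plus a between-cohort Cochran Q. Alleles are
#' aligned to the first cohort before pooling; an irreconcilable allele
#' pair raises an error.
#'
#' @param records List of per-cohort summary-statistics tibbles sharing
#'   `snp_id`, `effect_allele`, `other_allele`, `beta`, `se` (and
#'   optionally `n`).
#' @return Tibble with pooled `beta`, `se`, `p`, total `n`, `k_cohorts`,
#'   `q_cohort`, `q_cohort_p` per variant.
#' @export
meta_fixed <- function(records) {
  if (is.data.frame(records)) records <- list(records)
  if (length(records) < 1L) {
    abort("no cohorts supplied", class = "hcymr_validation_error")
  }
  purrr::walk(records, assert_cols,
              cols = c("snp_id", "effect_allele", "other_allele",
                       "beta", "se"),
              name = "records")
  ref <- records[[1]]
  aligned <- purrr::map(records, function(r) {
    r <- r[r$snp_id %in% ref$snp_id, ]
    m <- ref[match(r$snp_id, ref$snp_id), ]
    same <- r$effect_allele == m$effect_allele &
      r$other_allele == m$other_allele
    swapped <- r$effect_allele == m$other_allele &
      r$other_allele == m$effect_allele
    if (any(!(same | swapped))) {
      abort(paste0("allele mismatch not resolvable by flipping for: ",
                   paste(r$snp_id[!(same | swapped)], collapse = ", ")),
            class = "hcymr_validation_error")
    }
    r$beta[swapped] <- -r$beta[swapped]
    r$effect_allele <- m$effect_allele
    r$other_allele <- m$other_allele
    r
  })
  long <- dplyr::bind_rows(aligned, .id = "cohort")
  has_n <- "n" %in% names(long)
  has_eaf <- "eaf" %in% names(long)
  long |>
    dplyr::group_by(.data$snp_id, .data$effect_allele,
                    .data$other_allele) |>
    dplyr::summarise(
      pooled = sum(beta / se^2) / sum(1 / se^2),
      se_pooled = sqrt(1 / sum(1 / se^2)),
      q_cohort = sum((beta - pooled)^2 / se^2),
      k_cohorts = dplyr::n(),
      n = if (has_n) sum(n) else NA_integer_,
      eaf = if (has_eaf) mean(eaf, na.rm = TRUE) else NA_real_,
      .groups = "drop") |>
    dplyr::mutate(
      beta = .data$pooled, se = .data$se_pooled,
      p = 2 * pnorm(abs(.data$beta / .data$se), lower.tail = FALSE),
      q_cohort_p = ifelse(.data$k_cohorts > 1,
                          pchisq(.data$q_cohort,
                                 df = .data$k_cohorts - 1,
                                 lower.tail = FALSE), NA_real_),
      trait = "outcome") |>
    dplyr::select("snp_id", "effect_allele", "other_allele", "beta",
                  "se", "p", "n", "eaf", "trait", "k_cohorts",
                  "q_cohort", "q_cohort_p")
}

#' Inverse-variance weighted estimator
#'
#' Combines per-instrument Wald ratios with weights beta_x^2 / se_y^2:
#' \deqn{\hat\theta = \frac{\sum_i \beta_{Xi}\beta_{Yi}/\sigma_{Yi}^2}
#'                        {\sum_i \beta_{Xi}^2/\sigma_{Yi}^2},}
#' equivalent to weighted least squares of beta_y on beta_x through the
#' origin with weights 1/se_y^2. The fixed-effect SE is
#' (sum beta_x^2/se_y^2)^(-1/2); the multiplicative random-effects model
#' scales it by max(1, sqrt(Q/(k-1))). With one instrument the estimate
#' reduces exactly to the Wald ratio with se = se_y/|beta_x|.
#'
#' @param instr Harmonized instrument tibble.
#' @param model `"fixed"` or `"multiplicative_random"`.
#' @return An `mr_result` row with Cochran `Q`, `Q_df`, `Q_p` attached
#'   (for k >= 2).
#' @export
ivw <- function(instr, model = c("fixed", "multiplicative_random")) {
  model <- match.arg(model)
  instr <- check_instr(instr, 1L, "ivw")
  w <- instr$beta_x^2 / instr$se_y^2
  est <- sum(instr$beta_x * instr$beta_y / instr$se_y^2) / sum(w)
  se <- sqrt(1 / sum(w))
  k <- nrow(instr)
  if (k >= 2) {
    q <- cochran_q(instr, est)
    if (model == "multiplicative_random") {
      se <- se * max(1, sqrt(q$Q / (k - 1)))
    }
    new_mr_result(paste0("ivw_", model), est, se,
                  p = 2 * pnorm(abs(est / se), lower.tail = FALSE),
                  k = k, Q = q$Q, Q_df = q$df, Q_p = q$p)
  } else {
    new_mr_result(paste0("ivw_", model), est, se,
                  p = 2 * pnorm(abs(est / se), lower.tail = FALSE),
                  k = k)
  }
}

# weighted-median point estimate: linear interpolation of the weighted
# empirical CDF of the sorted per-instrument ratios at probability 0.5,
# using midpoint cumulative weights s_i = cum_i - w_i/2.
weighted_median_point <- function(ratios, weights) {
  ord <- order(ratios)
  r <- ratios[ord]
  w <- weights[ord] / sum(weights)
  s <- cumsum(w) - w / 2
  if (s[1] >= 0.5) return(r[1])
  k <- length(r)
  if (s[k] <= 0.5) return(r[k])
  j <- max(which(s <= 0.5))
  r[j] + (r[j + 1] - r[j]) * (0.5 - s[j]) / (s[j + 1] - s[j])
}

#' Weighted median estimator
#'
#' The weighted 50th percentile of the per-instrument ratio estimates
#' theta_i = beta_y/beta_x with weights beta_x^2/se_y^2, consistent when
#' at least half the weight comes from valid instruments. The SE is the
#' standard deviation of the estimator over `n_boot` parametric resamples
#' drawing beta_x* ~ N(beta_x, se_x^2), beta_y* ~ N(beta_y, se_y^2).
#'
#' @param instr Harmonized instrument tibble (k >= 3).
#' @param n_boot Bootstrap draws (default 2000).
#' @param seed Integer seed for the bootstrap.
#' @return An `mr_result` row.
#' @export
weighted_median <- function(instr, n_boot = 2000L, seed = 1L) {
  instr <- check_instr(instr, 3L, "weighted_median")
  ratios <- instr$beta_y / instr$beta_x
  w <- instr$beta_x^2 / instr$se_y^2
  est <- weighted_median_point(ratios, w)
  boots <- with_local_seed(derive_seed(seed, "median_boot"), {
    vapply(seq_len(n_boot), function(i) {
      bx <- rnorm(nrow(instr), instr$beta_x, instr$se_x)
      by <- rnorm(nrow(instr), instr$beta_y, instr$se_y)
      weighted_median_point(by / bx, bx^2 / instr$se_y^2)
    }, numeric(1))
  })
  se <- sd(boots)
  new_mr_result("weighted_median", est, se,
                p = 2 * pnorm(abs(est / se), lower.tail = FALSE),
                k = nrow(instr), se_method = sprintf(
                  "parametric_bootstrap(%d)", n_boot))
}

#' MR-Egger regression
#'
#' Weighted least squares of beta_y on beta_x with a free intercept and
#' weights 1/se_y^2, after orienting all instruments to beta_x >= 0. The
#' slope estimates the causal effect under the InSIDE assumption; the
#' intercept estimates average directional pleiotropy. Standard errors use
#' the estimated multiplicative dispersion RSS_w/(k-2) with a t reference
#' (k-2 degrees of freedom) for both slope and intercept — the original
#' estimator's convention, under which the intercept (pleiotropy) test is
#' exactly nominal for well-specified weights. (Some toolkits floor the
#' dispersion at 1, which makes the test conservative.)
#'
#' @param instr Harmonized instrument tibble (k >= 3).
#' @return An `mr_result` row: slope as the estimate, plus
#'   `egger_intercept`, `intercept_se`, `intercept_p` and `i2_gx`.
#' @export
mr_egger <- function(instr) {
  instr <- check_instr(instr, 3L, "mr_egger")
  instr <- orient_instr(instr)
  k <- nrow(instr)
  w <- 1 / instr$se_y^2
  x <- cbind(1, instr$beta_x)
  wls <- lm.fit(x * sqrt(w), instr$beta_y * sqrt(w))
  coefs <- wls$coefficients
  rss <- sum(wls$residuals^2)
  phi <- rss / (k - 2)
  xtx_inv <- chol2inv(qr.R(wls$qr))
  ses <- sqrt(diag(xtx_inv) * phi)
  slope <- coefs[2]
  slope_se <- ses[2]
  int <- coefs[1]
  int_se <- ses[1]
  new_mr_result(
    "mr_egger", unname(slope), unname(slope_se),
    p = 2 * pt(abs(slope / slope_se), df = k - 2, lower.tail = FALSE),
    k = k,
    egger_intercept = unname(int), intercept_se = unname(int_se),
    intercept_p = 2 * pt(abs(int / int_se), df = k - 2,
                         lower.tail = FALSE),
    i2_gx = i2_gx(instr))
}

#' Cochran Q heterogeneity statistic
#'
#' Q = sum_i w_i (theta_i - theta)^2 with per-instrument ratios
#' theta_i = beta_y/beta_x and weights w_i = beta_x^2/se_y^2; df = k - 1;
#' p from the chi-square upper tail. Low heterogeneity supports a shared
#' causal effect across instruments.
#'
#' @param instr Harmonized instrument tibble (k >= 2).
#' @param theta Reference causal estimate (e.g. the IVW estimate).
#' @return A list: `Q`, `df`, `p`.
#' @export
cochran_q <- function(instr, theta) {
  instr <- check_instr(instr, 2L, "cochran_q")
  ratios <- instr$beta_y / instr$beta_x
  w <- instr$beta_x^2 / instr$se_y^2
  q <- sum(w * (ratios - theta)^2)
  k <- nrow(instr)
  list(Q = q, df = k - 1L,
       p = pchisq(q, df = k - 1, lower.tail = FALSE))
}

#' I2GX weak-instrument / measurement-error statistic for MR-Egger
#'
#' Quantifies the relative dispersion of the (oriented) instrument-exposure
#' effects beyond their measurement error:
#' Q_GX = sum_i (beta_x_i - beta_bar_w)^2 / se_x_i^2 with beta_bar_w the
#' 1/se_x^2-weighted mean, and I2GX = max(0, (Q_GX - (k-1)) / Q_GX).
#' Values near 1 indicate the NO-Measurement-Error assumption holds and
#' MR-Egger is not attenuated by regression dilution.
#'
#' @param instr Harmonized instrument tibble (k >= 2).
#' @return A number in [0, 1); defined as 1 (with attribute
#'   `no_measurement_error`) when all se_x are zero.
#' @export
i2_gx <- function(instr) {
  instr <- check_instr(instr, 2L, "i2_gx")
  instr <- orient_instr(instr)
  if (all(instr$se_x == 0)) {
    return(structure(1, no_measurement_error = TRUE))
  }
  if (any(instr$se_x == 0)) {
    abort("mixed zero and positive se_x unsupported",
          class = "hcymr_validation_error")
  }
  w <- 1 / instr$se_x^2
  bbar <- sum(w * instr$beta_x) / sum(w)
  q_gx <- sum((instr$beta_x - bbar)^2 / instr$se_x^2)
  if (q_gx == 0) return(0)
  max(0, (q_gx - (nrow(instr) - 1)) / q_gx)
}

#' Run the full two-sample MR analysis
#'
#' Pools per-variant outcome associations across cohorts (fixed-effect
#' meta-analysis), harmonizes exposure and outcome summary statistics,
#' and runs IVW, weighted median and MR-Egger with Cochran Q and I2GX
#' diagnostics, returning a single structured report. The alternative
#' `mode = "pool_mr"` runs the estimators per cohort and pools the
#' causal estimates instead.
#'
#' @param exposure Exposure summary-statistics tibble.
#' @param outcome Outcome summary-statistics tibble or list of per-cohort
#'   tibbles.
#' @param ivw_model Passed to [ivw()]; with `"fixed"` (default) a note is
#'   attached suggesting multiplicative random effects when the Q p-value
#'   is below 0.05.
#' @param n_boot,seed Weighted-median bootstrap controls.
#' @param mode `"pool_outcome"` (meta-analyse outcome GWAS per variant,
#'   then one MR; default) or `"pool_mr"` (per-cohort MR, then pool).
#' @param drop_palindromic_maf Passed to [harmonize()].
#' @return An `mr_report` list: `instruments`, `results` (stacked
#'   `mr_result` rows), `Q`, `i2_gx`, `dropped`, `mode`.
#' @export
run_twosample <- function(exposure, outcome,
                          ivw_model = c("fixed", "multiplicative_random"),
                          n_boot = 2000L, seed = 1L,
                          mode = c("pool_outcome", "pool_mr"),
                          drop_palindromic_maf = 0.42) {
  ivw_model <- match.arg(ivw_model)
  mode <- match.arg(mode)
  cohorts <- if (is.data.frame(outcome)) list(outcome) else outcome

  run_one <- function(out_stats) {
    instr <- harmonize(exposure, out_stats,
                       drop_palindromic_maf = drop_palindromic_maf)
    if (nrow(instr) < 3L) {
      abort("fewer than 3 harmonizable instruments",
            class = "hcymr_validation_error")
    }
    res_ivw <- ivw(instr, model = ivw_model)
    res_med <- weighted_median(instr, n_boot = n_boot, seed = seed)
    res_egg <- mr_egger(instr)
    list(instr = instr, results = list(
      weighted_median = res_med, ivw = res_ivw, mr_egger = res_egg))
  }

  if (mode == "pool_outcome") {
    pooled <- meta_fixed(cohorts)
    one <- run_one(pooled)
    instr <- one$instr
    results <- one$results
  } else {
    per <- purrr::map(cohorts, run_one)
    instr <- per[[1]]$instr
    results <- purrr::map(
      setNames(names(per[[1]]$results), names(per[[1]]$results)),
      function(mth) {
        ests <- purrr::map_dbl(per, ~ .x$results[[mth]]$estimate)
        ses <- purrr::map_dbl(per, ~ .x$results[[mth]]$se)
        w <- 1 / ses^2
        est <- sum(w * ests) / sum(w)
        se <- sqrt(1 / sum(w))
        new_mr_result(per[[1]]$results[[mth]]$method[1], est, se,
                      p = 2 * pnorm(abs(est / se), lower.tail = FALSE),
                      k = per[[1]]$results[[mth]]$k_instruments[1])
      })
  }

  q <- cochran_q(instr, results$ivw$estimate[1])
  note <- if (ivw_model == "fixed" && q$p < 0.05) {
    "heterogeneity detected (Q p < 0.05): consider ivw_model = 'multiplicative_random'"
  } else {
    NA_character_
  }
  structure(list(
    instruments = instr,
    results = dplyr::bind_rows(results$weighted_median, results$ivw,
                               results$mr_egger),
    Q = q, i2_gx = as.numeric(i2_gx(instr)),
    dropped = attr(instr, "dropped"),
    mode = mode, note = note
  ), class = "mr_report")
}

#' @export
print.mr_report <- function(x, ...) {
  cat(sprintf("<mr_report: %d instruments, mode = %s>\n",
              nrow(x$instruments), x$mode))
  print(as.data.frame(x$results[
    , c("method", "estimate", "ci_low", "ci_high", "p")]),
    row.names = FALSE, digits = 4)
  cat(sprintf("Cochran Q = %.3f (df %d, p = %.3g); I2GX = %.1f%%\n",
              x$Q$Q, x$Q$df, x$Q$p, 100 * x$i2_gx))
  if (!is.na(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}

#' @export
tidy.mr_report <- function(x, ...) {
  dplyr::bind_rows(purrr::map(
    split(x$results, seq_len(nrow(x$results))),
    ~ tidy.mr_result(structure(.x, class = class(x$results)))))
}

#' @export
glance.mr_report <- function(x, ...) {
  tibble(k_instruments = nrow(x$instruments),
         Q = x$Q$Q, Q_df = x$Q$df, Q_p = x$Q$p,
         egger_intercept = x$results$egger_intercept[
           x$results$method == "mr_egger"],
         intercept_p = x$results$intercept_p[
           x$results$method == "mr_egger"],
         i2_gx = x$i2_gx, mode = x$mode)
}
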