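# mr_result: one-row tibble shared by every estimator. CI convention
# throughout: estimate -/+ 1.959964 * SE on the log-odds scale.

new_mr_result <- function(method, estimate, se, p, k, ...,
                          ci_mult = 1.959964) {
  extras <- tibble(...)
  out <- tibble(method = method, estimate = estimate, se = se,
                ci_low = estimate - ci_mult * se,
                ci_high = estimate + ci_mult * se,
                p = p, k_instruments = as.integer(k))
  if (ncol(extras) > 0) out <- dplyr::bind_cols(out, extras)
  structure(out, class = c("mr_result", class(tibble())))
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf(
    "<mr_result: %s  beta = %.4g (95%% CI %.4g, %.4g), p = %.3g, k = %d>\n",
    x$method[1], x$estimate[1], x$ci_low[1], x$ci_high[1], x$p[1],
    x$k_instruments[1]))
  invisible(x)
}

#' Tidy and summarize MR estimator results
#'
#' `tidy()` returns the estimate rows in broom's standard column layout
#' (MR-Egger yields a slope row and an intercept row); `glance()` returns
#' the one-row diagnostics (heterogeneity Q, Egger intercept, I2GX, first
#' stage F) where the estimator provides them.
#'
#' @param x An `mr_result`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.mr_result <- function(x, ...) {
  main <- tibble(
    method = x$method, term = "causal_effect", estimate = x$estimate,
    std.error = x$se, statistic = x$estimate / x$se, p.value = x$p,
    conf.low = x$ci_low, conf.high = x$ci_high
  )
  if ("egger_intercept" %in% names(x) && !is.na(x$egger_intercept[1])) {
    main <- dplyr::bind_rows(main, tibble(
      method = x$method, term = "intercept",
      estimate = x$egger_intercept, std.error = x$intercept_se,
      statistic = x$egger_intercept / x$intercept_se,
      p.value = x$intercept_p,
      conf.low = x$egger_intercept - 1.959964 * x$intercept_se,
      conf.high = x$egger_intercept + 1.959964 * x$intercept_se
    ))
  }
  main
}

#' @rdname tidy.mr_result
#' @export
glance.mr_result <- function(x, ...) {
  keep <- intersect(
    c("method", "k_instruments", "Q", "Q_df", "Q_p", "egger_intercept",
      "intercept_se", "intercept_p", "i2_gx", "f_stat", "se_method"),
    names(x))
  as_tibble(as.data.frame(x)[, keep, drop = FALSE])
}
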