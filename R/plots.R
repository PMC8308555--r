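#' Instrument scatter and funnel plots
#'
#' `plot_mr_scatter()` draws the harmonized per-instrument effects
#' (beta_x vs beta_y with 1-SE error bars) with the fitted IVW
#' (through-origin) and MR-Egger (free-intercept) lines;
#' `plot_mr_funnel()` draws per-instrument Wald ratios against their
#' precision, the standard asymmetry diagnostic for directional
#' pleiotropy. `autoplot()` on an `mr_report` dispatches to the scatter.
#'
#' @param instr Harmonized instrument tibble (from [harmonize()]).
#' @param report Optional `mr_report`; when given, fitted lines use its
#'   estimates.
#' @return A ggplot object.
#' @export
plot_mr_scatter <- function(instr, report = NULL) {
  instr <- orient_instr(check_instr(instr, 1L, "plot_mr_scatter"))
  res <- if (!is.null(report)) report$results else dplyr::bind_rows(
    ivw(instr), if (nrow(instr) >= 3) mr_egger(instr))
  ivw_b <- res$estimate[grepl("^ivw", res$method)][1]
  egg <- res[res$method == "mr_egger", ]
  p <- ggplot2::ggplot(instr, ggplot2::aes(x = .data$beta_x,
                                           y = .data$beta_y)) +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$beta_y - .data$se_y,
      ymax = .data$beta_y + .data$se_y), width = 0, colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(
      xmin = .data$beta_x - .data$se_x,
      xmax = .data$beta_x + .data$se_x), height = 0, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = 0, slope = ivw_b,
                         colour = "#2166AC") +
    ggplot2::labs(
      x = "per-allele effect on log-Hcy (SD)",
      y = "per-allele effect on MetS (log-odds)",
      title = "Instrument effects with IVW (blue) and MR-Egger (red) fits")
  if (nrow(egg)) {
    p <- p + ggplot2::geom_abline(intercept = egg$egger_intercept,
                                  slope = egg$estimate,
                                  colour = "#B2182B", linetype = 2)
  }
  p
}

#' @rdname plot_mr_scatter
#' @export
plot_mr_funnel <- function(instr, report = NULL) {
  instr <- orient_instr(check_instr(instr, 1L, "plot_mr_funnel"))
  df <- dplyr::mutate(
    instr, ratio = .data$beta_y / .data$beta_x,
    precision = abs(.data$beta_x) / .data$se_y)
  ivw_b <- if (!is.null(report)) {
    report$results$estimate[grepl("^ivw", report$results$method)][1]
  } else {
    ivw(instr)$estimate[1]
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ratio,
                                   y = .data$precision)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = ivw_b, colour = "#2166AC") +
    ggplot2::labs(x = "per-instrument causal ratio",
                  y = "instrument precision |beta_x| / se_y",
                  title = "Funnel plot of per-instrument ratios")
}

#' @rdname plot_mr_scatter
#' @param object An `mr_report`.
#' @param ... Unused.
#' @export
autoplot.mr_report <- function(object, ...) {
  plot_mr_scatter(object$instruments, object)
}
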