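#' Diagnostic and simulation plots
#'
#' Thin ggplot2 layers over the tidy result tables; every plot returns a
#' ggplot object that can be further customized.
#'
#' @name mv_plots
NULL

#' @describeIn mv_plots QQ plot of p-values on the -log10 scale with the
#'   pointwise 95% Beta order-statistic band and the genomic inflation
#'   factor in the subtitle.
#' @param p Numeric vector of p-values.
#' @param level Band coverage.
#' @export
plot_qq <- function(p, level = 0.95) {
  band <- qq_band(length(p), level = level)
  dat <- dplyr::mutate(band, observed = sort(p))
  lam <- genomic_inflation(pmax(p, 1e-300))
  ggplot2::ggplot(dat, ggplot2::aes(x = -log10(.data$expected))) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = -log10(.data$upper), ymax = -log10(.data$lower)),
      fill = "grey80"
    ) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point(ggplot2::aes(y = -log10(.data$observed)), size = 0.6) +
    ggplot2::labs(
      x = expression(-log[10] ~ "expected p"),
      y = expression(-log[10] ~ "observed p"),
      subtitle = sprintf("genomic inflation factor = %.3f", lam)
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn mv_plots Empirical false-positive rate per test and level,
#'   from [type1_error_study()], with the binomial concentration band.
#' @param result Tidy rejection table.
#' @export
plot_type1 <- function(result, level = 0.95) {
  band <- concentration_band(unique(result$alpha),
                             replicates = result$replicates[1],
                             level = level)
  ggplot2::ggplot(result, ggplot2::aes(x = factor(.data$alpha),
                                       y = .data$proportion,
                                       colour = .data$test)) +
    ggplot2::geom_errorbar(
      data = band,
      ggplot2::aes(x = factor(.data$alpha), ymin = .data$lower,
                   ymax = .data$upper),
      inherit.aes = FALSE, width = 0.3, colour = "grey60"
    ) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::labs(x = "nominal level", y = "empirical false-positive rate") +
    ggplot2::theme_minimal()
}

#' @describeIn mv_plots Power curves from [power_study()], faceted by the
#'   spread increment `s`, power against the mean shift `r`.
#' @export
plot_power <- function(result) {
  ggplot2::ggplot(result, ggplot2::aes(x = .data$r, y = .data$proportion,
                                       colour = .data$test)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~s, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "mean shift r", y = "empirical power") +
    ggplot2::theme_minimal()
}

#' @describeIn mv_plots Scatter of a null statistic pair from
#'   [independence_diagnostics()] with the Pearson correlation in the
#'   subtitle.
#' @param x An `mv_independence` object.
#' @param pair Character vector of two test names present in the object.
#' @export
plot_statistic_pair <- function(x, pair = c("WT", "LEVENE")) {
  stopifnot(inherits(x, "mv_independence"), length(pair) == 2,
            all(pair %in% names(x$statistics)))
  rho <- cor(x$statistics[[pair[1]]], x$statistics[[pair[2]]])
  ggplot2::ggplot(x$statistics,
                  ggplot2::aes(x = .data[[pair[1]]], y = .data[[pair[2]]])) +
    ggplot2::geom_point(alpha = 0.15, size = 0.4) +
    ggplot2::labs(subtitle = sprintf("Pearson correlation = %.4f", rho)) +
    ggplot2::theme_minimal()
}
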