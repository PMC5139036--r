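#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a calibration fit
#'
#' `tidy()` returns the per-probe results computed on the calibrated
#' (residualized) matrix; `glance()` a one-row summary of the fit.
#'
#' @param x An `mv_calibration` from [calibrate_study()].
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.mv_calibration <- function(x, ...) {
  x$results
}

#' @rdname tidy.mv_calibration
#' @exportS3Method generics::glance
glance.mv_calibration <- function(x, ...) {
  tibble::tibble(
    n_probes = x$n_probes,
    n_samples = x$n_samples,
    n_robust = length(x$robust_probe_ids),
    n_significant_pcs = sum(x$pc_screen$significant),
    n_adjusted_pcs = sum(x$pc_screen$adjusted %||% x$pc_screen$significant),
    lambda_before = x$lambda_before,
    lambda_after = x$lambda_after,
    tau = x$tau,
    tau_pc = x$tau_pc,
    robust = x$robust
  )
}

#' @rdname tidy.mv_calibration
#' @exportS3Method generics::tidy
tidy.mv_independence <- function(x, ...) {
  x$correlations
}
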