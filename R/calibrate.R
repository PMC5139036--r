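#' Per-probe heterogeneity tests for an expression study
#'
#' Runs the selected two-group tests on every probe, splitting samples by
#' condition. Computation is fully vectorized across probes.
#'
#' @param study An [expression_study()].
#' @param tests Character vector of test names among
#'   `ST, WT, STSD, F, LEVENE, BF, IMVT, FWT, BFWT, SMVT, LRT`.
#' @param matrix Optional replacement matrix (e.g. residualized expression)
#'   with the same dimnames as `study$matrix`.
#' @param adjust If `TRUE` and IMVT is among the tests, append `q_imvt`
#'   (Benjamini-Hochberg) and `bonferroni_imvt` (significance at the
#'   Bonferroni-corrected 0.05 level).
#'
#' @return A wide tibble: `probe_id`, then `statistic_<test>` and
#'   `p_<test>` per test, plus adjustment columns.
#' @examples
#' study <- simulate_study(n_probes = 100, n_per_group = c(10, 10), seed = 3)
#' test_probes(study, tests = c("WT", "LEVENE", "IMVT"))
#' @export
test_probes <- function(study, tests = c("WT", "LEVENE", "IMVT", "SMVT"),
                        matrix = NULL, adjust = TRUE) {
  stopifnot(inherits(study, "expression_study"))
  m <- if (is.null(matrix)) study$matrix else matrix
  sp <- .split_by_condition(study, m)
  res <- .row_tests(sp$g1, sp$g2, tests)
  out <- tibble::tibble(probe_id = rownames(m))
  for (nm in names(res)) {
    out[[paste0("statistic_", tolower(nm))]] <- res[[nm]]$statistic
    out[[paste0("p_", tolower(nm))]] <- res[[nm]]$p
  }
  if (adjust && "p_imvt" %in% names(out)) {
    out$q_imvt <- bh_fdr(out$p_imvt)
    out$bonferroni_imvt <-
      out$p_imvt < bonferroni_threshold(0.05, nrow(out))
  }
  out
}

#' Principal components of the samples in an expression study
#'
#' PCA of the samples-by-probes submatrix after probe-wise mean-centering
#' (no scaling: normalized intensities share a scale; set `scale.` to
#' override). At most `n_samples - 1` non-trivial components exist.
#'
#' @inheritParams test_probes
#' @param probe_subset Optional character vector of probe IDs (default all).
#' @param scale. Scale probes to unit variance before PCA.
#' @return A list with `scores` (samples x components, rownames = sample
#'   IDs), `variance_proportions`, and `sdev`.
#' @export
pca_sample_scores <- function(study, probe_subset = NULL, matrix = NULL,
                              scale. = FALSE) {
  stopifnot(inherits(study, "expression_study"))
  m <- if (is.null(matrix)) study$matrix else matrix
  if (!is.null(probe_subset)) {
    if (!length(probe_subset)) rlang::abort("`probe_subset` is empty")
    m <- m[probe_subset, , drop = FALSE]
  }
  if (ncol(m) < 3) rlang::abort("insufficient samples for PCA (need >= 3)")
  pc <- prcomp(t(m), center = TRUE, scale. = scale.)
  vp <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x, variance_proportions = vp, sdev = pc$sdev)
}

#' Screen principal components for condition-associated heterogeneity
#'
#' Each component's per-sample scores are treated as a two-group sample
#' split by condition and tested for mean heterogeneity (Welch t) and
#' variance heterogeneity (Levene). A component is flagged when either
#' p-value falls below `tau_pc` (unadjusted; the goal is sensitive capture
#' of condition-associated background structure, not inference on the
#' components).
#'
#' @param pca A fit from [pca_sample_scores()].
#' @param condition Factor of length n_samples with two levels.
#' @param tau_pc Screening level.
#' @return A tibble `pc`, `variance_proportion`, `p_wt`, `p_lf`,
#'   `significant`.
#' @export
screen_pcs <- function(pca, condition, tau_pc = 0.05) {
  scores <- pca$scores
  idx <- condition == levels(condition)[1]
  t_scores <- t(scores)
  pmat <- .row_p_matrix(t_scores[, idx, drop = FALSE],
                        t_scores[, !idx, drop = FALSE],
                        tests = c("WT", "LEVENE"))
  tibble::tibble(
    pc = seq_len(ncol(scores)),
    variance_proportion = pca$variance_proportions[seq_len(ncol(scores))],
    p_wt = pmat[, "WT"],
    p_lf = pmat[, "LEVENE"],
    significant = pmat[, "WT"] < tau_pc | pmat[, "LEVENE"] < tau_pc
  )
}

#' Residualize an expression matrix against covariates and components
#'
#' Per-probe ordinary least-squares residuals of expression on an intercept,
#' the covariate columns, and the supplied background component scores. The
#' condition label is never part of the design, so condition-driven signal
#' survives while structure captured by the design is removed.
#'
#' @inheritParams test_probes
#' @param pc_scores Optional samples x components matrix of background
#'   scores to adjust for.
#' @param covariates Character vector of covariate names in
#'   `study$phenotype` (default: all of them).
#' @return A residual matrix with the dimnames of the input.
#' @export
residualize <- function(study, pc_scores = NULL, covariates = study$covariates,
                        matrix = NULL) {
  stopifnot(inherits(study, "expression_study"))
  m <- if (is.null(matrix)) study$matrix else matrix
  X <- cbind(intercept = rep(1, ncol(m)))
  for (cv in covariates) X <- cbind(X, study$phenotype[[cv]])
  if (!is.null(pc_scores)) X <- cbind(X, pc_scores)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    rlang::abort("collinear calibration design (rank-deficient)")
  }
  Q <- qr.Q(qx)
  res <- m - (m %*% Q) %*% t(Q)
  dimnames(res) <- dimnames(m)
  res
}

#' Background-structure calibration of an expression study
#'
#' The full calibration pipeline for separating informative mean/variance
#' heterogeneity (caused by the condition) from impediment heterogeneity
#' (caused by covariates and latent background structure):
#'
#' 1. Test every probe on the raw matrix (Welch t + Levene + IMVT) and
#'    record the genomic inflation factor.
#' 2. Keep "robust" probes: neither mean nor variance heterogeneity at
#'    level `tau`.
#' 3. Compute background principal components from the robust probes and
#'    flag components associated with the condition
#'    ([screen_pcs()]).
#' 4. Residualize the robust probes on covariates plus flagged components,
#'    re-test, and drop probes now violating the thresholds (repeated
#'    `passes - 1` times).
#' 5. Recompute background components from the final robust set, flag
#'    again, residualize the full matrix on covariates plus the flagged
#'    components, re-test every probe, and record the post-calibration
#'    inflation factor.
#'
#' With `robust = FALSE` the components are instead computed from all
#' probes ("global" components). That naive variant over-adjusts: global
#' components absorb part of the condition-driven signal of truly
#' differential probes, deflating the inflation factor below 1 and costing
#' power.
#'
#' @inheritParams test_probes
#' @param tau Robustness level: probes with `p_WT <= tau` or
#'   `p_Levene <= tau` are excluded from the background set.
#' @param tau_pc Component-screening level, see [screen_pcs()].
#' @param covariates Covariate names to adjust for (default all).
#' @param robust Use the robust-probe background (recommended); `FALSE`
#'   reproduces the naive global-component adjustment.
#' @param passes Number of selection passes (2 = the before/after
#'   procedure; larger values iterate toward a fixed point).
#' @param noise_floor_mult Robust mode only: a flagged component enters the
#'   adjustment design only if its eigenvalue exceeds this multiple of the
#'   median eigenvalue. Components at the isotropic noise floor are
#'   unidentifiable rotations of noise; flagging them means they were
#'   selected for chance condition correlation, and regressing them out
#'   provably absorbs part of every probe's condition contrast (deflating
#'   all tests). The robust-probe selection itself manufactures such a
#'   component: truncating condition-heterogeneous probes suppresses
#'   variance along the condition contrast, so a trailing component of the
#'   robust submatrix aligns with the condition indicator. Set to 0 to
#'   adjust for every flagged component. The naive mode ignores the floor —
#'   that is precisely the over-adjustment it reproduces.
#'
#' @return An object of class `mv_calibration` with elements
#'   `robust_probe_ids`, `pc_screen` (tibble from [screen_pcs()]),
#'   `pc_scores`, `variance_proportions`, `residual_matrix`, `results`
#'   (per-probe tibble from [test_probes()] on the residuals, with BH and
#'   Bonferroni adjustment), `results_raw`, `lambda_before`, `lambda_after`,
#'   and the settings used. `tidy()` returns the per-probe results,
#'   `glance()` a one-row summary.
#' @examples
#' study <- simulate_study(n_probes = 300, n_per_group = c(15, 15), seed = 5)
#' fit <- calibrate_study(study)
#' glance(fit)
#' @export
calibrate_study <- function(study, tau = 0.05, tau_pc = 0.05,
                            covariates = study$covariates,
                            tests = c("WT", "LEVENE", "IMVT", "SMVT"),
                            robust = TRUE, passes = 2,
                            noise_floor_mult = 1.5) {
  stopifnot(inherits(study, "expression_study"), passes >= 1)
  tests <- union(toupper(tests), c("WT", "LEVENE", "IMVT"))
  results_raw <- test_probes(study, tests = tests)
  lambda_before <- genomic_inflation(results_raw$p_imvt)

  adjusted_pcs <- function(pca, screen) {
    keep <- screen$significant
    if (robust && noise_floor_mult > 0) {
      ev <- pca$sdev^2
      keep <- keep & ev[screen$pc] > noise_floor_mult * median(ev)
    }
    screen$pc[keep]
  }

  if (robust) {
    keep <- results_raw$probe_id[
      results_raw$p_wt > tau & results_raw$p_levene > tau
    ]
    if (!length(keep)) rlang::abort("no robust probes at tau")
    for (pass in seq_len(passes - 1)) {
      pca <- pca_sample_scores(study, probe_subset = keep)
      screen <- screen_pcs(pca, study$condition, tau_pc)
      sig <- pca$scores[, adjusted_pcs(pca, screen), drop = FALSE]
      res_m <- residualize(study, pc_scores = sig, covariates = covariates,
                           matrix = study$matrix[keep, , drop = FALSE])
      re <- test_probes(study, tests = c("WT", "LEVENE"), matrix = res_m,
                        adjust = FALSE)
      keep2 <- keep[re$p_wt > tau & re$p_levene > tau]
      if (!length(keep2)) rlang::abort("no robust probes at tau")
      if (identical(keep2, keep)) { keep <- keep2; break }
      keep <- keep2
    }
    background_ids <- keep
  } else {
    background_ids <- results_raw$probe_id
  }

  pca <- pca_sample_scores(study, probe_subset = background_ids)
  screen <- screen_pcs(pca, study$condition, tau_pc)
  adj <- adjusted_pcs(pca, screen)
  screen$adjusted <- screen$pc %in% adj
  sig_scores <- pca$scores[, adj, drop = FALSE]
  residual_matrix <- residualize(study, pc_scores = sig_scores,
                                 covariates = covariates)
  results <- test_probes(study, tests = tests, matrix = residual_matrix)
  lambda_after <- genomic_inflation(results$p_imvt)

  structure(
    list(
      robust_probe_ids = background_ids,
      pc_screen = screen,
      pc_scores = pca$scores,
      variance_proportions = pca$variance_proportions,
      residual_matrix = residual_matrix,
      results = results,
      results_raw = results_raw,
      lambda_before = lambda_before,
      lambda_after = lambda_after,
      tau = tau, tau_pc = tau_pc, robust = robust,
      noise_floor_mult = noise_floor_mult,
      covariates = covariates, n_probes = nrow(study$matrix),
      n_samples = ncol(study$matrix)
    ),
    class = "mv_calibration"
  )
}

#' @export
print.mv_calibration <- function(x, ...) {
  cat(sprintf(
    paste0(
      "mv_calibration: %d probes, %d samples\n",
      "  background: %s, %d robust probes, %d adjusted PC(s)\n",
      "  genomic inflation: %.3f before -> %.3f after calibration\n"
    ),
    x$n_probes, x$n_samples,
    if (x$robust) "robust-probe" else "global (naive)",
    length(x$robust_probe_ids),
    sum(x$pc_screen$adjusted %||% x$pc_screen$significant),
    x$lambda_before, x$lambda_after
  ))
  invisible(x)
}

#' Select robust background probes
#'
#' Convenience wrapper around [calibrate_study()] returning just the final
#' robust-probe IDs: probes displaying neither mean nor variance
#' heterogeneity at level `tau`, before and after adjusting for the
#' significant background components and covariates.
#'
#' @inheritParams calibrate_study
#' @return Character vector of probe IDs.
#' @export
select_robust_probes <- function(study, tau = 0.05, tau_pc = 0.05,
                                 covariates = study$covariates, passes = 2) {
  if (tau == 0) return(rownames(study$matrix))
  calibrate_study(study, tau = tau, tau_pc = tau_pc, covariates = covariates,
                  passes = passes)$robust_probe_ids
}

#' Genomic inflation factor
#'
#' The ratio of the median association statistic to its expectation under
#' the null: p-values are transformed to upper-tail chi-squared(1) quantiles
#' and the median is divided by the chi-squared(1) median (about 0.4549).
#' Values near 1 indicate proper type-I control; values well above 1
#' indicate confounding or anti-conservative tests, values below 1
#' over-adjustment.
#'
#' @param p Numeric vector of p-values in (0, 1\] (at least 10).
#' @return A single number, lambda.
#' @examples
#' genomic_inflation(runif(1000))
#' @export
genomic_inflation <- function(p) {
  if (length(p) < 10) rlang::abort("need at least 10 p-values")
  if (any(p <= 0 | p > 1, na.rm = TRUE) || anyNA(p)) {
    rlang::abort("p-values must lie in (0, 1]")
  }
  if (all(p == 1)) {
    rlang::warn("all p-values equal to 1; lambda = 0")
    return(0)
  }
  median(qchisq(p, df = 1, lower.tail = FALSE)) / qchisq(0.5, df = 1)
}

#' Pointwise concentration band for a QQ plot of p-values
#'
#' For rank `i` of `n` sorted p-values the null order statistic is
#' Beta(i, n - i + 1); the band is its central `level` interval. On the
#' -log10 scale the band widens toward the smallest ranks.
#'
#' @param n_tests Number of p-values.
#' @param level Coverage.
#' @return A tibble `rank`, `expected` (null median), `lower`, `upper` (all
#'   on the p scale, ascending).
#' @export
qq_band <- function(n_tests, level = 0.95) {
  stopifnot(n_tests >= 1, level > 0, level < 1)
  i <- seq_len(n_tests)
  a <- (1 - level) / 2
  tibble::tibble(
    rank = i,
    expected = qbeta(0.5, i, n_tests - i + 1),
    lower = qbeta(a, i, n_tests - i + 1),
    upper = qbeta(1 - a, i, n_tests - i + 1)
  )
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (wraps
#' `stats::p.adjust(method = "BH")`).
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  p.adjust(p, method = "BH")
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise level.
#' @param n_tests Number of tests (at least 1).
#' @return `alpha / n_tests`.
#' @examples
#' bonferroni_threshold(0.05, 22283)
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  stopifnot(n_tests >= 1)
  alpha / n_tests
}
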