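#' Simulate a two-condition expression study with latent structure
#'
#' Generates a probes-by-samples matrix emulating the statistical anatomy of
#' a normalized microarray study: a dominant global factor shared by all
#' probes (so the first principal component carries almost all the
#' variance), a condition-mean-shifted minor factor and a
#' condition-variance-inflated minor factor (latent structure that confounds
#' naive per-probe testing), covariates (an age-like numeric, mildly
#' confounded with condition, and a derived binary) with probe-level
#' effects, and a set of planted mean-variance differentially expressed
#' (MVDE) probes whose truth table is returned for recovery scoring.
#'
#' Planted effects are parameterized like the Monte-Carlo engines: probe
#' `i`'s condition-2 values gain a mean shift `r * noise_sd` and have their
#' probe-level noise scaled by `1 + s`. By default the planted set cycles
#' through mean-only `(r, 0)`, variance-only `(0, s)`, and dual `(r, s)`
#' effects.
#'
#' @param n_probes Number of probes.
#' @param n_per_group Length-2 integer vector of samples per condition.
#' @param n_planted Number of planted MVDE probes (taken from the head of
#'   the probe list).
#' @param planted_r,planted_s Planted effect magnitudes (mean shift in units
#'   of `noise_sd`; spread multiplier `1 + s`).
#' @param bright_frac Fraction of probes in the high-intensity stratum that
#'   carries the dominant global factor. Concentrating the factor in a
#'   minority of bright probes mirrors normalized microarray data, where the
#'   leading component holds most of the total variance yet a typical probe
#'   is not background-dominated.
#' @param bright_loading Loading of bright probes on the global factor; at
#'   the defaults the first PC accounts for over 90% of total variance.
#' @param ordinary_background Loading of the remaining probes on the global
#'   factor.
#' @param mean_factor_shift Condition shift of the mean-heterogeneity latent
#'   factor's per-sample scores.
#' @param var_factor_inflation Spread increment of the
#'   variance-heterogeneity latent factor under condition 2.
#' @param minor_loading_sd SD of per-probe loadings on the two minor
#'   factors.
#' @param covariate_frac Fraction of probes with covariate effects.
#' @param noise_sd Per-probe residual noise SD.
#' @param family Noise family, `"normal"` or `"laplace"` (scaled to unit
#'   variance).
#' @param seed Integer seed for exact reproducibility.
#'
#' @return An `expression_study` with an extra element `truth`: a tibble
#'   `probe_id`, `r`, `s` for the planted probes.
#' @examples
#' study <- simulate_study(n_probes = 200, n_per_group = c(10, 10), seed = 7)
#' study$truth
#' @export
simulate_study <- function(n_probes = 5000, n_per_group = c(40, 40),
                           n_planted = 50, planted_r = 1.5, planted_s = 1.5,
                           bright_frac = 0.03, bright_loading = 20,
                           ordinary_background = 0.1,
                           mean_factor_shift = 0.45,
                           var_factor_inflation = 1,
                           minor_loading_sd = 0.35,
                           covariate_frac = 0.2, noise_sd = 0.5,
                           family = c("normal", "laplace"), seed = NULL) {
  family <- match.arg(family)
  stopifnot(length(n_per_group) == 2, all(n_per_group >= 2),
            n_planted <= n_probes, planted_s > -1)
  if (!is.null(seed)) set.seed(seed)
  n1 <- n_per_group[1]; n2 <- n_per_group[2]
  n <- n1 + n2
  condition <- rep(c("control", "case"), c(n1, n2))
  cond2 <- condition == "case"

  probe_ids <- sprintf("probe_%04d", seq_len(n_probes))
  sample_ids <- sprintf("sample_%02d", seq_len(n))

  # covariates: age-like numeric and a binary menopause-like indicator
  # derived from it; independent of condition, so they add probe-level
  # variance that calibration removes without absorbing condition contrast
  age <- rnorm(n, mean = 50, sd = 5)
  menopause <- as.integer(age + rnorm(n, sd = 3) > 51)

  # latent factors (per-sample scores)
  f_bg <- rnorm(n)                                        # dominant, null
  f_mean <- mean_factor_shift * (cond2 - 0.5) + rnorm(n, sd = 0.5)
  f_var <- rnorm(n) * (1 + var_factor_inflation * cond2)

  # per-probe loadings and covariate coefficients; the bright stratum is
  # drawn outside the planted block so planted effects stay visible on the
  # probe's own scale
  n_bright <- round(bright_frac * n_probes)
  eligible <- setdiff(seq_len(n_probes), seq_len(n_planted))
  bright <- sample(eligible, min(n_bright, length(eligible)))
  l_bg <- rep(ordinary_background, n_probes)
  l_bg[bright] <- bright_loading * (1 + rnorm(length(bright), sd = 0.1))
  l_mean <- rnorm(n_probes, sd = minor_loading_sd)
  l_var <- rnorm(n_probes, sd = minor_loading_sd)
  has_cov <- runif(n_probes) < covariate_frac
  b_age <- ifelse(has_cov, rnorm(n_probes, sd = 0.02), 0)
  b_men <- ifelse(has_cov, rnorm(n_probes, sd = 0.2), 0)

  noise <- if (family == "normal") {
    matrix(rnorm(n_probes * n), n_probes, n)
  } else {
    matrix(.rlaplace(n_probes * n) / sqrt(2), n_probes, n)
  }

  # planted truth: cycle mean-only, variance-only, dual
  r_vec <- numeric(n_probes); s_vec <- numeric(n_probes)
  if (n_planted > 0) {
    kind <- rep_len(c("mean", "var", "dual"), n_planted)
    idx <- seq_len(n_planted)
    r_vec[idx] <- ifelse(kind != "var", planted_r, 0)
    s_vec[idx] <- ifelse(kind != "mean", planted_s, 0)
  }
  scale_mat <- 1 + outer(s_vec, as.numeric(cond2))
  shift_mat <- noise_sd * outer(r_vec, as.numeric(cond2))

  mat <- rnorm(n_probes, mean = 8, sd = 1) +
    outer(l_bg, f_bg) + outer(l_mean, f_mean) + outer(l_var, f_var) +
    outer(b_age, age - mean(age)) + outer(b_men, menopause - mean(menopause)) +
    shift_mat + noise_sd * scale_mat * noise
  dimnames(mat) <- list(probe_ids, sample_ids)

  phenotype <- tibble::tibble(
    sample_id = sample_ids, condition = condition,
    age = age, menopause = menopause
  )
  study <- expression_study(mat, phenotype)
  study$truth <- tibble::tibble(
    probe_id = probe_ids[seq_len(n_planted)],
    r = r_vec[seq_len(n_planted)], s = s_vec[seq_len(n_planted)]
  )
  study
}
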