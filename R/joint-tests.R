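#' Combine a mean and a variance p-value by Fisher's method
#'
#' Under the dual null hypothesis (equal means and equal variances) the mean-
#' and variance-heterogeneity statistics are independent whenever the joint
#' sampling distribution is spherically symmetric, so
#' \eqn{-2(\ln p_{mean} + \ln p_{var})} is referred to a chi-squared
#' distribution with 4 degrees of freedom.
#'
#' @param p_mean,p_var Component p-values in \[0, 1\].
#' @param p_floor Smallest admissible p-value fed to the logarithm; smaller
#'   values (including exact zeros) are clamped with a warning. Must be
#'   positive and at most 1e-300.
#' @param probe_id Optional identifier carried into the result.
#'
#' @return A one-row tibble with columns `test`, `statistic`, `df1`, `df2`,
#'   `p_value`, `probe_id`.
#' @examples
#' fisher_combine(0.05, 0.05)
#' @export
fisher_combine <- function(p_mean, p_var, p_floor = 1e-300, probe_id = NULL) {
  stopifnot(is.numeric(p_floor), length(p_floor) == 1,
            p_floor > 0, p_floor <= 1e-300)
  for (p in list(p_mean, p_var)) {
    if (!is.numeric(p) || length(p) != 1 || is.na(p) || p < 0 || p > 1) {
      rlang::abort("invalid p-value: components must be single values in [0, 1]")
    }
  }
  if (p_mean < p_floor || p_var < p_floor) {
    rlang::warn(sprintf(
      "component p-value below %.3g for probe %s; clamped before taking logs",
      p_floor, .probe_label(probe_id)
    ))
    p_mean <- max(p_mean, p_floor)
    p_var <- max(p_var, p_floor)
  }
  stat <- -2 * (log(p_mean) + log(p_var))
  new_test_result("IMVT", stat, 4, NA,
                  pchisq(stat, 4, lower.tail = FALSE), probe_id)
}

.fisher_two_group <- function(group1, group2, mean_test, variance_test,
                              label, probe_id, p_floor = 1e-300) {
  mean_fun <- if (is.function(mean_test)) {
    mean_test
  } else {
    switch(toupper(mean_test),
      WT = welch_t, ST = student_t, STSD = stsd_t,
      rlang::abort("unknown mean test")
    )
  }
  var_fun <- switch(toupper(variance_test),
    LEVENE = levene_test, BF = brown_forsythe_test, F = var_f_test,
    rlang::abort("unknown variance test")
  )
  pm <- mean_fun(group1, group2, probe_id)$p_value
  pv <- var_fun(group1, group2, probe_id)$p_value
  res <- fisher_combine(pm, pv, p_floor = p_floor, probe_id = probe_id)
  res$test <- label
  res
}

#' Integrative mean-variance test and its Fisher-combination variants
#'
#' `imvt()` combines the Welch t p-value with the Levene p-value — the
#' recommended pairing, robust beyond normality. `fwt()` pairs Welch t with
#' the two-sample F test (most powerful under exact normality, fragile
#' otherwise) and `bfwt()` with the Brown-Forsythe test. All three refer
#' \eqn{-2(\ln p_{mean} + \ln p_{var})} to \eqn{\chi^2_4}.
#'
#' @inheritParams two_group_tests
#' @param mean_test The mean-heterogeneity component: `"WT"` (default),
#'   `"ST"`, `"STSD"`, or a plug-in function with signature
#'   `(group1, group2, probe_id)` returning a tibble with a `p_value` column
#'   (e.g. a moderated t-test supplied by the user).
#' @param p_floor Passed to [fisher_combine()].
#' @return A one-row tibble; see [two_group_tests].
#' @examples
#' imvt(rnorm(40), rnorm(40, sd = 1.5))
#' @export
imvt <- function(group1, group2, probe_id = NULL, mean_test = "WT",
                 p_floor = 1e-300) {
  .fisher_two_group(group1, group2, mean_test, "LEVENE", "IMVT", probe_id,
                    p_floor)
}

#' @rdname imvt
#' @export
fwt <- function(group1, group2, probe_id = NULL, mean_test = "WT",
                p_floor = 1e-300) {
  .fisher_two_group(group1, group2, mean_test, "F", "FWT", probe_id, p_floor)
}

#' @rdname imvt
#' @export
bfwt <- function(group1, group2, probe_id = NULL, mean_test = "WT",
                 p_floor = 1e-300) {
  .fisher_two_group(group1, group2, mean_test, "BF", "BFWT", probe_id, p_floor)
}

#' Split an overall level into equal per-component levels
#'
#' The separate mean and variance test (SMVT) rejects the dual null when
#' either component rejects at its own level; by null independence the
#' overall type I error is \eqn{\alpha = \alpha_1 + \alpha_2 -
#' \alpha_1\alpha_2}. The equal split solving this identity is
#' \eqn{\alpha_1 = \alpha_2 = 1 - \sqrt{1 - \alpha}}.
#'
#' @param alpha Overall level in (0, 1).
#' @return A tibble with columns `alpha`, `alpha1`, `alpha2`.
#' @examples
#' smvt_split_alpha(0.05)
#' @export
smvt_split_alpha <- function(alpha) {
  stopifnot(is.numeric(alpha), all(alpha > 0), all(alpha < 1))
  a1 <- 1 - sqrt(1 - alpha)
  tibble::tibble(alpha = alpha, alpha1 = a1, alpha2 = a1)
}

#' Separate mean and variance tests of the dual null
#'
#' Applies the Welch t test to mean equality and the Levene test to variance
#' equality, rejecting the dual null if either component p-value falls below
#' its split level. The reported combined p-value is the Sidak-style
#' transform \eqn{p = 1 - (1 - \min(p_{WT}, p_{LF}))^2}, a package
#' convention chosen so that the decision "p <= alpha" reproduces the split
#' rule exactly at the equal split \eqn{\alpha_1 = \alpha_2 = 1 -
#' \sqrt{1-\alpha}}.
#'
#' @inheritParams two_group_tests
#' @return A one-row tibble; `statistic` is \eqn{\min(p_{WT}, p_{LF})} and
#'   `p_value` the combined p-value.
#' @examples
#' smvt(rnorm(40), rnorm(40, 2))
#' @export
smvt <- function(group1, group2, probe_id = NULL) {
  pm <- welch_t(group1, group2, probe_id)$p_value
  pv <- levene_test(group1, group2, probe_id)$p_value
  pmin_ <- min(pm, pv)
  new_test_result("SMVT", pmin_, NA, NA, 1 - (1 - pmin_)^2, probe_id)
}

#' Two-sample normal likelihood ratio test of the dual null
#'
#' The likelihood ratio compares condition-specific normal fits (separate
#' means and variances) with a single normal fit pooled over all samples;
#' \eqn{-2 \ln \Lambda} is referred to \eqn{\chi^2_2}. The ratio is computed
#' in log space to avoid under/overflow at large n. Valid under normality
#' and large samples only: the chi-squared approximation inflates type I
#' error at small n and under heavy tails.
#'
#' @inheritParams two_group_tests
#' @return A one-row tibble; see [two_group_tests].
#' @examples
#' lrt_test(c(1, 2, 3), c(2, 4, 6))
#' @export
lrt_test <- function(group1, group2, probe_id = NULL) {
  check_two_group(group1, group2, probe_id)
  n1 <- length(group1); n2 <- length(group2)
  n <- n1 + n2
  mle1 <- (n1 - 1) / n1 * var(group1)
  mle2 <- (n2 - 1) / n2 * var(group2)
  mu <- (sum(group1) + sum(group2)) / n
  mlep <- (sum((group1 - mu)^2) + sum((group2 - mu)^2)) / n
  if (mle1 <= 0 || mle2 <= 0 || mlep <= 0) {
    rlang::abort(sprintf("degenerate LRT for probe %s: zero variance",
                         .probe_label(probe_id)))
  }
  log_lambda <- n1 / 2 * log(mle1) + n2 / 2 * log(mle2) - n / 2 * log(mlep)
  stat <- -2 * log_lambda
  new_test_result("LRT", stat, 2, NA,
                  pchisq(stat, 2, lower.tail = FALSE), probe_id)
}
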