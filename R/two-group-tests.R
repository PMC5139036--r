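#' Two-group mean- and variance-heterogeneity tests
#'
#' Atomic two-sample tests on the expression values of a single probe split
#' by condition. Three mean-heterogeneity tests — classical Student t
#' ([student_t()]), Welch t with Satterthwaite degrees of freedom
#' ([welch_t()]), and Student t on data standardized by condition-specific
#' standard deviations ([stsd_t()]) — and three variance-heterogeneity tests
#' — the two-sample F ratio ([var_f_test()]), the Levene test on absolute
#' deviations from the group mean ([levene_test()]), and the Brown-Forsythe
#' test on absolute deviations from the group median
#' ([brown_forsythe_test()]).
#'
#' All tests are two-sided. Each returns a one-row tibble so results for
#' many probes can be row-bound and piped into dplyr verbs.
#'
#' @param group1,group2 Numeric vectors of expression values under the two
#'   conditions; each must have length at least 2 and contain only finite
#'   values.
#' @param probe_id Optional identifier carried into the result (and into any
#'   warning raised on a degenerate input).
#'
#' @return A tibble with one row and columns `test`, `statistic`, `df1`,
#'   `df2` (`NA` for tests with a single degrees-of-freedom parameter),
#'   `p_value`, and `probe_id`.
#'
#' @details
#' Degenerate inputs follow fixed conventions: a zero pooled variance with
#' equal group means yields statistic 0 and p-value 1 (with a warning); a
#' zero pooled variance with unequal means is an error, as are a zero
#' denominator variance for the F ratio and a zero group variance for the
#' standardized Student t. The Levene-type tests return p = 1 when both the
#' between- and within-group spread of the absolute deviations vanish and
#' p = 0 (logged) when only the within-group spread does.
#'
#' @examples
#' welch_t(c(1, 2, 3), c(2, 4, 6))
#' levene_test(rnorm(10), rnorm(10, sd = 2))
#' @name two_group_tests
NULL

new_test_result <- function(test, statistic, df1, df2, p_value,
                            probe_id = NA_character_) {
  tibble::tibble(
    test = test,
    statistic = as.numeric(statistic),
    df1 = as.numeric(df1),
    df2 = as.numeric(df2),
    p_value = as.numeric(p_value),
    probe_id = if (is.null(probe_id)) NA_character_ else as.character(probe_id)
  )
}

check_two_group <- function(group1, group2, probe_id = NULL,
                            call = rlang::caller_env()) {
  for (nm in c("group1", "group2")) {
    g <- if (nm == "group1") group1 else group2
    if (!is.numeric(g)) {
      rlang::abort(sprintf("`%s` must be numeric.", nm), call = call)
    }
    if (length(g) < 2) {
      rlang::abort(
        sprintf("`%s` must have at least 2 values (sample variance must exist).", nm),
        call = call
      )
    }
    if (!all(is.finite(g))) {
      rlang::abort(sprintf("`%s` contains non-finite values.", nm), call = call)
    }
  }
  invisible(NULL)
}

.probe_label <- function(probe_id) {
  if (is.null(probe_id) || is.na(probe_id[1])) "<unnamed probe>" else probe_id[1]
}

#' @rdname two_group_tests
#' @export
student_t <- function(group1, group2, probe_id = NULL) {
  check_two_group(group1, group2, probe_id)
  n1 <- length(group1); n2 <- length(group2)
  m1 <- mean(group1); m2 <- mean(group2)
  df <- n1 + n2 - 2
  vp <- ((n1 - 1) * var(group1) + (n2 - 1) * var(group2)) / df
  if (vp == 0) {
    if (m1 == m2) {
      rlang::warn(sprintf(
        "zero pooled variance with equal means for probe %s; statistic set to 0",
        .probe_label(probe_id)
      ))
      return(new_test_result("ST", 0, df, NA, 1, probe_id))
    }
    rlang::abort(sprintf(
      "zero pooled variance with unequal means for probe %s", .probe_label(probe_id)
    ))
  }
  stat <- (m1 - m2) / sqrt(vp * (1 / n1 + 1 / n2))
  new_test_result("ST", stat, df, NA, 2 * pt(abs(stat), df, lower.tail = FALSE),
                  probe_id)
}

#' @rdname two_group_tests
#' @export
welch_t <- function(group1, group2, probe_id = NULL) {
  check_two_group(group1, group2, probe_id)
  n1 <- length(group1); n2 <- length(group2)
  m1 <- mean(group1); m2 <- mean(group2)
  v1 <- var(group1); v2 <- var(group2)
  if (v1 == 0 && v2 == 0) {
    if (m1 == m2) {
      rlang::warn(sprintf(
        "zero variance in both groups with equal means for probe %s; statistic set to 0",
        .probe_label(probe_id)
      ))
      return(new_test_result("WT", 0, n1 + n2 - 2, NA, 1, probe_id))
    }
    rlang::abort(sprintf(
      "zero variance in both groups with unequal means for probe %s",
      .probe_label(probe_id)
    ))
  }
  se2 <- v1 / n1 + v2 / n2
  stat <- (m1 - m2) / sqrt(se2)
  nu <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
  new_test_result("WT", stat, nu, NA, 2 * pt(abs(stat), nu, lower.tail = FALSE),
                  probe_id)
}

#' @rdname two_group_tests
#' @export
stsd_t <- function(group1, group2, probe_id = NULL) {
  check_two_group(group1, group2, probe_id)
  s1 <- stats::sd(group1); s2 <- stats::sd(group2)
  if (s1 == 0 || s2 == 0) {
    rlang::abort(sprintf(
      "zero variance for probe %s: STSD undefined", .probe_label(probe_id)
    ))
  }
  # Divide each group by its own sample SD; no centering, so the mean signal
  # survives while a pure scale change is removed.
  res <- student_t(group1 / s1, group2 / s2, probe_id)
  res$test <- "STSD"
  res
}

#' @rdname two_group_tests
#' @export
var_f_test <- function(group1, group2, probe_id = NULL) {
  check_two_group(group1, group2, probe_id)
  v1 <- var(group1); v2 <- var(group2)
  if (v2 == 0) {
    rlang::abort(sprintf(
      "zero denominator variance for probe %s", .probe_label(probe_id)
    ))
  }
  n1 <- length(group1); n2 <- length(group2)
  stat <- v1 / v2
  p <- 2 * min(
    pf(stat, n1 - 1, n2 - 1),
    pf(stat, n1 - 1, n2 - 1, lower.tail = FALSE)
  )
  new_test_result("F", stat, n1 - 1, n2 - 1, min(p, 1), probe_id)
}

.levene_type <- function(group1, group2, center, test, probe_id) {
  n1 <- length(group1); n2 <- length(group2)
  z1 <- abs(group1 - center(group1))
  z2 <- abs(group2 - center(group2))
  zb1 <- mean(z1); zb2 <- mean(z2)
  zb <- (n1 * zb1 + n2 * zb2) / (n1 + n2)
  df2 <- n1 + n2 - 2
  num <- df2 * (n1 * (zb1 - zb)^2 + n2 * (zb2 - zb)^2)
  den <- sum((z1 - zb1)^2) + sum((z2 - zb2)^2)
  if (den == 0) {
    if (num == 0) {
      return(new_test_result(test, 0, 1, df2, 1, probe_id))
    }
    rlang::warn(sprintf(
      "constant absolute deviations within groups for probe %s; p set to 0",
      .probe_label(probe_id)
    ))
    return(new_test_result(test, Inf, 1, df2, 0, probe_id))
  }
  stat <- num / den
  new_test_result(test, stat, 1, df2, pf(stat, 1, df2, lower.tail = FALSE),
                  probe_id)
}

#' @rdname two_group_tests
#' @export
levene_test <- function(group1, group2, probe_id = NULL) {
  check_two_group(group1, group2, probe_id)
  .levene_type(group1, group2, mean, "LEVENE", probe_id)
}

#' @rdname two_group_tests
#' @export
brown_forsythe_test <- function(group1, group2, probe_id = NULL) {
  check_two_group(group1, group2, probe_id)
  .levene_type(group1, group2, median, "BF", probe_id)
}
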