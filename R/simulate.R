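#' Monte-Carlo engines for type-I-error, power, and independence studies
#'
#' The study design throughout: group 1 is drawn from the standard member of
#' the family (N(0,1) or standard Laplace with scale 1) and group 2 as
#' `r + (1 + s) * draw`, so `r` is the mean shift and `s` the spread
#' increment — for the normal family group 2 is exactly N(r, (1+s)^2), and
#' for the Laplace family the same location/scale construction keeps `(r, s)`
#' comparable across families. All tests within one call are evaluated on the
#' same simulated replicates (paired comparisons), and a fixed `seed` makes
#' results bit-reproducible.
#'
#' @name simulation_engine
NULL

.rlaplace <- function(n) {
  u <- runif(n) - 0.5
  -sign(u) * log(1 - 2 * abs(u))
}

.draw_matrix <- function(family, nrow, ncol) {
  x <- switch(family,
    normal = rnorm(nrow * ncol),
    laplace = .rlaplace(nrow * ncol),
    rlang::abort("`family` must be \"normal\" or \"laplace\"")
  )
  matrix(x, nrow, ncol)
}

.simulate_matrices <- function(family, n1, n2, r, s, replicates) {
  stopifnot(s > -1, replicates >= 1, n1 >= 2, n2 >= 2)
  list(
    g1 = .draw_matrix(family, replicates, n1),
    g2 = r + (1 + s) * .draw_matrix(family, replicates, n2)
  )
}

#' @describeIn simulation_engine Draw one two-group sample as a tidy tibble
#'   with columns `group` (factor `"1"`/`"2"`) and `value`.
#' @param family `"normal"` or `"laplace"`.
#' @param n1,n2 Group sample sizes (at least 2).
#' @param r Mean shift applied to group 2.
#' @param s Spread increment for group 2 (multiplier `1 + s`; `s > -1`).
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @export
draw_two_group <- function(family = c("normal", "laplace"), n1 = 40, n2 = 40,
                           r = 0, s = 0, seed = NULL) {
  family <- match.arg(family)
  if (!is.null(seed)) set.seed(seed)
  m <- .simulate_matrices(family, n1, n2, r, s, 1L)
  tibble::tibble(
    group = factor(rep(c("1", "2"), c(n1, n2))),
    value = c(m$g1[1, ], m$g2[1, ])
  )
}

#' @describeIn simulation_engine Per-replicate statistics and p-values for
#'   the selected tests, as a long tibble with columns `replicate`, `test`,
#'   `statistic`, `p_value`.
#' @param replicates Number of Monte-Carlo replicates.
#' @param tests Character vector of test names among
#'   `ST, WT, STSD, F, LEVENE, BF, IMVT, FWT, BFWT, SMVT, LRT`.
#' @export
simulate_statistics <- function(family = c("normal", "laplace"), n1 = 40,
                                n2 = 40, r = 0, s = 0, replicates = 1000,
                                seed = NULL,
                                tests = c("WT", "ST", "F", "LEVENE", "BF")) {
  family <- match.arg(family)
  if (!is.null(seed)) set.seed(seed)
  m <- .simulate_matrices(family, n1, n2, r, s, replicates)
  res <- .row_tests(m$g1, m$g2, tests)
  purrr::imap(res, function(x, nm) {
    tibble::tibble(replicate = seq_len(replicates), test = nm,
                   statistic = x$statistic, p_value = x$p)
  }) %>%
    dplyr::bind_rows()
}

.rejection_table <- function(pmat, alpha, family, n1, n2, r, s) {
  replicates <- nrow(pmat)
  tidyr::expand_grid(test = colnames(pmat), alpha = alpha) %>%
    dplyr::mutate(
      family = family, n1 = n1, n2 = n2, r = r, s = s,
      rejections = purrr::map2_int(.data$test, .data$alpha,
                                   ~ sum(pmat[, .x] <= .y)),
      replicates = replicates,
      proportion = .data$rejections / replicates,
      mc_se = sqrt(.data$proportion * (1 - .data$proportion) / replicates)
    ) %>%
    dplyr::select("test", "family", "n1", "n2", "r", "s", "alpha",
                  "rejections", "replicates", "proportion", "mc_se")
}

#' @describeIn simulation_engine Empirical false-positive rate of each test
#'   under the dual null (`r = 0`, `s = 0`) at each level in `alpha`.
#'   Returns a tidy tibble with columns `test`, `family`, `n1`, `n2`, `r`,
#'   `s`, `alpha`, `rejections`, `replicates`, `proportion`, `mc_se`.
#' @param alpha Significance level(s) in (0, 1).
#' @export
type1_error_study <- function(family = c("normal", "laplace"), n1 = 40,
                              n2 = 40, replicates = 10000, seed = NULL,
                              alpha = c(0.01, 0.05),
                              tests = c("WT", "STSD", "IMVT", "FWT", "BFWT",
                                        "SMVT", "LRT")) {
  family <- match.arg(family)
  stopifnot(all(alpha > 0), all(alpha < 1))
  if (!is.null(seed)) set.seed(seed)
  m <- .simulate_matrices(family, n1, n2, 0, 0, replicates)
  pmat <- .row_p_matrix(m$g1, m$g2, tests)
  .rejection_table(pmat, alpha, family, n1, n2, r = 0, s = 0)
}

#' @describeIn simulation_engine Empirical power over a grid of `(r, s)`
#'   pairs, supplied as a data frame with columns `r` and `s` (a null point
#'   `r = s = 0` is allowed and then estimates the type-I rate). Same output
#'   columns as `type1_error_study()`.
#' @param grid Data frame with numeric columns `r` and `s`.
#' @export
power_study <- function(grid, family = c("normal", "laplace"), n1 = 40,
                        n2 = 40, replicates = 10000, seed = NULL,
                        alpha = 0.05,
                        tests = c("WT", "STSD", "IMVT", "SMVT")) {
  family <- match.arg(family)
  stopifnot(is.data.frame(grid), all(c("r", "s") %in% names(grid)),
            all(grid$s > -1), length(alpha) == 1, alpha > 0, alpha < 1)
  if (!is.null(seed)) set.seed(seed)
  purrr::pmap(grid[c("r", "s")], function(r, s) {
    m <- .simulate_matrices(family, n1, n2, r, s, replicates)
    pmat <- .row_p_matrix(m$g1, m$g2, tests)
    .rejection_table(pmat, alpha, family, n1, n2, r, s)
  }) %>%
    dplyr::bind_rows()
}

#' @describeIn simulation_engine Central 95% (or `level`) band for an
#'   empirical rejection proportion of a correctly calibrated test:
#'   `alpha +/- z * sqrt(alpha (1 - alpha) / replicates)`, clipped to
#'   \[0, 1\]. Vectorized over `alpha`.
#' @param level Coverage of the band.
#' @export
concentration_band <- function(alpha, replicates, level = 0.95) {
  stopifnot(all(alpha > 0), all(alpha < 1), replicates >= 1)
  z <- stats::qnorm(1 - (1 - level) / 2)
  half <- z * sqrt(alpha * (1 - alpha) / replicates)
  tibble::tibble(
    alpha = alpha, replicates = replicates,
    lower = pmax(alpha - half, 0), upper = pmin(alpha + half, 1)
  )
}

#' @describeIn simulation_engine Null statistic-pair diagnostics: simulates
#'   under the dual null and returns an object with the per-replicate
#'   statistics (wide tibble, one column per test) and all pairwise Pearson
#'   correlations (long tibble `test1`, `test2`, `correlation`). Under
#'   spherically symmetric sampling the mean-test/variance-test correlations
#'   concentrate near zero.
#' @export
independence_diagnostics <- function(family = c("normal", "laplace"),
                                     n1 = 40, n2 = 40, replicates = 10000,
                                     seed = NULL,
                                     tests = c("WT", "ST", "F", "LEVENE",
                                               "BF")) {
  family <- match.arg(family)
  if (!is.null(seed)) set.seed(seed)
  m <- .simulate_matrices(family, n1, n2, 0, 0, replicates)
  res <- .row_tests(m$g1, m$g2, tests)
  stats_tbl <- tibble::as_tibble(lapply(res, `[[`, "statistic"))
  cmat <- cor(as.matrix(stats_tbl))
  pairs <- which(upper.tri(cmat), arr.ind = TRUE)
  cors <- tibble::tibble(
    test1 = rownames(cmat)[pairs[, 1]],
    test2 = colnames(cmat)[pairs[, 2]],
    correlation = cmat[pairs]
  )
  structure(
    list(statistics = stats_tbl, correlations = cors,
         family = family, n1 = n1, n2 = n2, replicates = replicates),
    class = "mv_independence"
  )
}

#' @export
print.mv_independence <- function(x, ...) {
  cat(sprintf(
    "Null statistic-pair diagnostics: %s family, n1 = %d, n2 = %d, %d replicates\n",
    x$family, x$n1, x$n2, x$replicates
  ))
  print(x$correlations)
  invisible(x)
}
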