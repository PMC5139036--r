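# Tests of the dual null (mean and variance equality)

test_that("fisher_combine matches the chi-squared(4) reference", {
  expect_equal(fisher_combine(1, 1)$statistic, 0)
  expect_equal(fisher_combine(1, 1)$p_value, 1)

  res <- fisher_combine(0.05, 0.05)
  expect_equal(res$statistic, -4 * log(0.05), tolerance = 1e-12)
  # survival of chi-squared(4): exp(-x/2) (1 + x/2)
  x <- -4 * log(0.05)
  expect_equal(res$p_value, exp(-x / 2) * (1 + x / 2), tolerance = 1e-12)
  expect_equal(res$p_value, 0.01747866, tolerance = 1e-6)

  # monotone in each argument over a grid
  grid <- seq(0.01, 0.99, length.out = 20)
  pm <- outer(grid, grid,
              Vectorize(function(a, b) fisher_combine(a, b)$p_value))
  expect_true(all(diff(pm) > 0))       # rows: increasing in p_mean
  expect_true(all(t(diff(t(pm))) > 0)) # cols: increasing in p_var

  expect_error(fisher_combine(1.2, 0.5), "invalid p-value")
  expect_error(fisher_combine(0.5, -1), "invalid p-value")
  expect_warning(out <- fisher_combine(0, 0.5), "clamped")
  expect_true(is.finite(out$statistic))
})

test_that("imvt and variants compose their component tests", {
  set.seed(11)
  s <- random_two_group(12, 15)
  p_wt <- welch_t(s$g1, s$g2)$p_value
  p_lf <- levene_test(s$g1, s$g2)$p_value
  p_f <- var_f_test(s$g1, s$g2)$p_value
  p_bf <- brown_forsythe_test(s$g1, s$g2)$p_value

  expect_equal(imvt(s$g1, s$g2)$statistic, -2 * (log(p_wt) + log(p_lf)),
               tolerance = 1e-12)
  expect_equal(fwt(s$g1, s$g2)$statistic, -2 * (log(p_wt) + log(p_f)),
               tolerance = 1e-12)
  expect_equal(bfwt(s$g1, s$g2)$statistic, -2 * (log(p_wt) + log(p_bf)),
               tolerance = 1e-12)
  expect_equal(imvt(s$g1, s$g1)$p_value, 1)

  # worked example: composition of the Welch and Levene examples
  want <- oracle_fisher(oracle_welch(c(1, 2, 3), c(2, 4, 6))$p,
                        oracle_levene(c(1, 2, 3), c(2, 4, 6))$p)
  got <- imvt(c(1, 2, 3), c(2, 4, 6))
  expect_equal(got$statistic, want$statistic, tolerance = 1e-10)
  expect_equal(got$p_value, want$p, tolerance = 1e-10)

  # plug-in slot for a user-supplied mean test
  plug <- function(group1, group2, probe_id = NULL) {
    new_test_result("PLUG", 0, 1, NA, 0.5, probe_id)
  }
  expect_equal(imvt(s$g1, s$g2, mean_test = plug)$statistic,
               -2 * (log(0.5) + log(p_lf)), tolerance = 1e-12)
})

test_that("smvt split level solves alpha = a1 + a2 - a1 a2", {
  sp <- smvt_split_alpha(0.05)
  expect_equal(sp$alpha1, 1 - sqrt(0.95), tolerance = 1e-15)
  expect_equal(sp$alpha1 + sp$alpha2 - sp$alpha1 * sp$alpha2, 0.05,
               tolerance = 1e-12)
  # experiment-wide threshold for 22,283 probes
  expect_equal(smvt_split_alpha(0.05 / 22283)$alpha1, 1.12e-6,
               tolerance = 5e-3)
})

test_that("smvt combined p reproduces the split decision rule exactly", {
  set.seed(12)
  for (i in 1:200) {
    p_pair <- runif(2)
    p_smvt <- 1 - (1 - min(p_pair))^2
    for (alpha in c(0.001, 0.01, 0.05, 0.2)) {
      expect_identical(p_smvt <= alpha,
                       min(p_pair) <= 1 - sqrt(1 - alpha))
    }
  }
  s <- random_two_group(10, 10)
  res <- smvt(s$g1, s$g2)
  pmin_ <- min(welch_t(s$g1, s$g2)$p_value, levene_test(s$g1, s$g2)$p_value)
  expect_equal(res$p_value, 1 - (1 - pmin_)^2, tolerance = 1e-12)
  expect_equal(smvt(s$g1, s$g1)$p_value, 1)
})

test_that("smvt null rejection matches alpha1 + alpha2 - alpha1 alpha2", {
  x <- simulate_statistics("normal", 20, 20, replicates = 5000, seed = 13,
                           tests = c("WT", "LEVENE"))
  p <- tidyr::pivot_wider(x[, c("replicate", "test", "p_value")],
                          names_from = "test", values_from = "p_value")
  a1 <- 0.03; a2 <- 0.08
  rate <- mean(p$WT <= a1 | p$LEVENE <= a2)
  expected <- a1 + a2 - a1 * a2
  expect_lt(abs(rate - expected),
            3 * sqrt(expected * (1 - expected) / 5000))
})

test_that("lrt matches its closed form and is non-negative", {
  res <- lrt_test(c(1, 2, 3), c(2, 4, 6))
  expect_equal(res$statistic, -2 * log(1 / 8), tolerance = 1e-12)
  expect_equal(res$p_value, 0.125, tolerance = 1e-12)

  set.seed(14)
  for (i in 1:30) {
    s <- random_two_group()
    got <- lrt_test(s$g1, s$g2)
    want <- oracle_lrt(s$g1, s$g2)
    expect_equal(got$statistic, want$statistic, tolerance = 1e-10)
    expect_gte(got$statistic, 0)
  }
  expect_error(lrt_test(c(1, 1, 1), c(1, 2, 3)), "degenerate")
})

test_that("null statistics of mean and variance tests are uncorrelated", {
  d <- independence_diagnostics("normal", 40, 40, replicates = 10000,
                                seed = 15)
  cors <- tidy(d)
  pick <- function(a, b) {
    cors$correlation[(cors$test1 == a & cors$test2 == b) |
                     (cors$test1 == b & cors$test2 == a)]
  }
  # MC bound at R = 10,000 is about 0.02; allow 3 SE
  expect_lt(abs(pick("WT", "LEVENE")), 0.03)
  expect_lt(abs(pick("WT", "F")), 0.03)
  expect_equal(pick("WT", "ST"), 1, tolerance = 1e-12)
  expect_gt(pick("LEVENE", "BF"), 0.95)

  # independence + chi-squared(4) reference => uniform IMVT p under the null
  x <- simulate_statistics("normal", 40, 40, replicates = 10000, seed = 16,
                           tests = "IMVT")
  expect_lt(suppressWarnings(ks.test(x$p_value, "punif")$statistic), 0.025)
})
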