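# Background-structure calibration

make_null_study <- function(n_probes = 200, n = 20, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n_probes * n), n_probes, n,
              dimnames = list(sprintf("p%03d", seq_len(n_probes)),
                              sprintf("s%02d", seq_len(n))))
  expression_study(
    m, data.frame(sample_id = colnames(m),
                  condition = rep(c("a", "b"), each = n / 2))
  )
}

test_that("pca_sample_scores returns a valid spectrum", {
  study <- make_null_study(100, 20, seed = 31)
  pca <- pca_sample_scores(study)
  vp <- pca$variance_proportions
  expect_equal(sum(vp), 1, tolerance = 1e-10)
  expect_true(all(diff(vp) <= 1e-12))
  expect_true(all(vp >= 0))
  expect_lte(sum(vp > 1e-12), ncol(study$matrix) - 1)

  # planted rank-1 structure dominates
  set.seed(32)
  f <- rnorm(20)
  m1 <- outer(rnorm(100, sd = 2), f) + 1e-3 * matrix(rnorm(2000), 100, 20)
  dimnames(m1) <- dimnames(study$matrix)
  s1 <- expression_study(m1, study$phenotype)
  expect_gt(pca_sample_scores(s1)$variance_proportions[1], 0.99)

  expect_error(pca_sample_scores(study, probe_subset = character()), "empty")
})

test_that("screen_pcs flags constructed condition-associated components", {
  set.seed(33)
  n <- 40
  cond <- rep(c("a", "b"), each = n / 2)
  f_shift <- ifelse(cond == "b", 1.5, 0) + rnorm(n, sd = 0.4)
  f_infl <- rnorm(n) * ifelse(cond == "b", 3, 1)
  m <- rbind(
    outer(rnorm(150, sd = 2), rnorm(n)),      # null factor, dominant
    outer(2 + rnorm(50, sd = 0.2), f_shift),  # mean-shifted factor
    outer(2 + rnorm(50, sd = 0.2), f_infl)    # variance-inflated factor
  ) + 0.1 * matrix(rnorm(250 * n), 250, n)
  dimnames(m) <- list(sprintf("p%03d", 1:250), sprintf("s%02d", 1:n))
  study <- expression_study(m, data.frame(sample_id = colnames(m),
                                          condition = cond))
  pca <- pca_sample_scores(study)
  scr <- screen_pcs(pca, study$condition)
  sig <- scr[scr$significant, ]
  expect_gte(nrow(sig), 2)
  # among the three leading components one is flagged for mean and one for
  # variance heterogeneity
  lead <- scr[scr$pc <= 3, ]
  expect_true(any(lead$p_wt < 1e-4))
  expect_true(any(lead$p_lf < 0.01))
  # a null component with identical scores across conditions is not flagged
  expect_false(all(scr$significant))
})

test_that("residualize returns OLS residuals orthogonal to the design", {
  study <- make_null_study(50, 20, seed = 34)
  study$phenotype$age <- rnorm(20, 50, 5)
  study$covariates <- "age"
  scores <- matrix(rnorm(40), 20, 2)
  res <- residualize(study, pc_scores = scores)
  X <- cbind(1, study$phenotype$age, scores)
  expect_lt(max(abs(res %*% X)), 1e-8)
  # a probe equal to a design column residualizes to zero
  m2 <- study$matrix
  m2[1, ] <- study$phenotype$age
  res2 <- residualize(study, pc_scores = scores, matrix = m2)
  expect_lt(max(abs(res2[1, ])), 1e-8)
  # collinear design is rejected
  expect_error(
    residualize(study, pc_scores = cbind(study$phenotype$age)),
    "collinear"
  )
})

test_that("genomic inflation behaves as a median-chi-squared ratio", {
  set.seed(35)
  p <- runif(22283)
  # sampling SD of the median-based lambda at this size is about 0.02
  expect_equal(genomic_inflation(p), 1, tolerance = 0.06)
  expect_gt(genomic_inflation(p / 2), 1)
  expect_equal(genomic_inflation(rep(0.5, 11)), 1, tolerance = 1e-12)
  expect_error(genomic_inflation(runif(5)), "at least 10")
  expect_warning(l <- genomic_inflation(rep(1, 20)), "lambda = 0")
  expect_equal(l, 0)
})

test_that("qq band follows the Beta order-statistic law", {
  b1 <- qq_band(1)
  expect_equal(b1$lower, 0.025, tolerance = 1e-12)
  expect_equal(b1$upper, 0.975, tolerance = 1e-12)

  b <- qq_band(500)
  # band half-width on the -log10 scale widens toward the smallest ranks
  w <- log10(b$upper) - log10(b$lower)
  expect_gt(w[1], w[250])
  expect_gt(w[250], w[499])

  # null p-values mostly stay inside the pointwise band
  set.seed(36)
  inside <- replicate(20, {
    p <- sort(runif(500))
    mean(p >= b$lower & p <= b$upper)
  })
  expect_gte(mean(inside), 0.93)
})

test_that("bh_fdr matches the brute-force step-up oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  set.seed(37)
  for (i in 1:100) {
    p <- runif(sample(1:40, 1))
    q <- bh_fdr(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p))
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
  expect_equal(bonferroni_threshold(0.1, 10), 0.01)
  expect_equal(bonferroni_threshold(0.3, 1), 0.3)
})

test_that("robust selection retains most probes of a null study", {
  study <- make_null_study(400, 40, seed = 38)
  keep <- select_robust_probes(study)
  # per-probe exclusion probability is at most about 0.1 at tau = 0.05
  expect_gte(length(keep), 0.85 * 400)
  expect_identical(select_robust_probes(study, tau = 0),
                   rownames(study$matrix))
})

test_that("planted heterogeneous probes are excluded from the robust set", {
  study <- simulate_study(n_probes = 600, n_per_group = c(30, 30),
                          n_planted = 30, seed = 39)
  fit <- calibrate_study(study)
  planted_kept <- intersect(fit$robust_probe_ids, study$truth$probe_id)
  expect_lte(length(planted_kept), 3)
})

test_that("test_probes returns one row per probe with adjustment columns", {
  study <- make_null_study(60, 16, seed = 40)
  res <- test_probes(study, tests = c("WT", "LEVENE", "IMVT"))
  expect_equal(nrow(res), 60)
  expect_true(all(c("probe_id", "statistic_wt", "p_wt", "p_levene",
                    "p_imvt", "q_imvt", "bonferroni_imvt") %in% names(res)))
  expect_equal(res$q_imvt, bh_fdr(res$p_imvt))
})
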