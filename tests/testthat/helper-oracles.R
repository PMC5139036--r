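# Brute-force oracles transcribed term by term from the displayed formulas,
# written with explicit sums and loops so they stay independent of the
# package's vectorized implementations.

oracle_moments <- function(g) {
  n <- length(g)
  m <- sum(g) / n
  v <- sum((g - m)^2) / (n - 1)
  list(n = n, m = m, v = v)
}

oracle_student <- function(g1, g2) {
  a <- oracle_moments(g1); b <- oracle_moments(g2)
  df <- a$n + b$n - 2
  vp <- ((a$n - 1) * a$v + (b$n - 1) * b$v) / df
  stat <- (1 / a$n + 1 / b$n)^(-1 / 2) * (a$m - b$m) / sqrt(vp)
  list(statistic = stat, df = df,
       p = 2 * stats::pt(abs(stat), df, lower.tail = FALSE))
}

oracle_welch <- function(g1, g2) {
  a <- oracle_moments(g1); b <- oracle_moments(g2)
  stat <- (a$m - b$m) / sqrt(a$v / a$n + b$v / b$n)
  nu <- (a$v / a$n + b$v / b$n)^2 /
    (a$v^2 / (a$n^2 * (a$n - 1)) + b$v^2 / (b$n^2 * (b$n - 1)))
  list(statistic = stat, df = nu,
       p = 2 * stats::pt(abs(stat), nu, lower.tail = FALSE))
}

oracle_stsd <- function(g1, g2) {
  a <- oracle_moments(g1); b <- oracle_moments(g2)
  oracle_student(g1 / sqrt(a$v), g2 / sqrt(b$v))
}

oracle_f <- function(g1, g2) {
  a <- oracle_moments(g1); b <- oracle_moments(g2)
  stat <- a$v / b$v
  # evaluate each tail directly to avoid cancellation in 1 - CDF
  lo <- stats::pf(stat, a$n - 1, b$n - 1)
  hi <- stats::pf(stat, a$n - 1, b$n - 1, lower.tail = FALSE)
  list(statistic = stat, df = c(a$n - 1, b$n - 1),
       p = min(2 * min(lo, hi), 1))
}

# shared Levene-type F-ratio with an arbitrary centering function
oracle_levene_type <- function(g1, g2, center) {
  groups <- list(g1, g2)
  n <- lengths(groups)
  z <- lapply(groups, function(g) abs(g - center(g)))
  zbar_c <- vapply(z, mean, 0)
  zbar <- sum(unlist(z)) / sum(n)
  num <- (sum(n) - 2) * sum(n * (zbar_c - zbar)^2)
  den <- 0
  for (c in 1:2) for (j in seq_len(n[c])) den <- den + (z[[c]][j] - zbar_c[c])^2
  stat <- num / den
  list(statistic = stat, df = c(1, sum(n) - 2),
       p = stats::pf(stat, 1, sum(n) - 2, lower.tail = FALSE))
}

oracle_levene <- function(g1, g2) oracle_levene_type(g1, g2, mean)
oracle_bf <- function(g1, g2) oracle_levene_type(g1, g2, stats::median)

oracle_lrt <- function(g1, g2) {
  n1 <- length(g1); n2 <- length(g2); n <- n1 + n2
  a <- oracle_moments(g1); b <- oracle_moments(g2)
  mu <- (sum(g1) + sum(g2)) / n
  lambda <- ((n1 - 1) / n1 * a$v)^(n1 / 2) * ((n2 - 1) / n2 * b$v)^(n2 / 2) /
    ((sum((g1 - mu)^2) + sum((g2 - mu)^2)) / n)^(n / 2)
  stat <- -2 * log(lambda)
  list(statistic = stat, df = 2,
       p = stats::pchisq(stat, 2, lower.tail = FALSE))
}

oracle_fisher <- function(p_mean, p_var) {
  stat <- -2 * (log(p_mean) + log(p_var))
  list(statistic = stat, p = stats::pchisq(stat, 4, lower.tail = FALSE))
}

# step-up BH by the definition: q_(i) = min over j >= i of p_(j) * n / j
oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  q_sorted <- numeric(n)
  for (i in seq_len(n)) {
    best <- Inf
    for (j in i:n) best <- min(best, p[ord[j]] * n / j)
    q_sorted[i] <- min(best, 1)
  }
  q <- numeric(n)
  q[ord] <- q_sorted
  q
}

random_two_group <- function(n1 = NULL, n2 = NULL) {
  if (is.null(n1)) n1 <- sample(3:20, 1)
  if (is.null(n2)) n2 <- sample(3:20, 1)
  list(g1 = rnorm(n1, sd = runif(1, 0.5, 3)),
       g2 = rnorm(n2, mean = runif(1, -1, 1), sd = runif(1, 0.5, 3)))
}
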