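test_that("signed-rank test matches exact enumeration", {
  expect_equal(oneSampleSignedRank(c(-3, -1, 1, 3, -2, 2))$p, 1.0)
  expect_equal(oneSampleSignedRank(-(1:6))$p, 2 / 64)
  set.seed(61)
  for (b in 1:20) {
    v <- round(rnorm(sample(5:10, 1)), 1)
    v <- v[v != 0]
    if (length(v) < 5) next
    expect_equal(oneSampleSignedRank(v)$p, oracleSignedRankP(v))
  }
  expect_error(oneSampleSignedRank(c(0, 0, 0)), "zero")
  expect_error(oneSampleSignedRank(c(1, -1, 2, 0)), "at least 5")
})

test_that("signed-rank normal approximation holds the level at n = 30", {
  set.seed(62)
  B <- 1000
  rej <- mean(replicate(B, oneSampleSignedRank(rnorm(30))$p < 0.05))
  expect_lt(abs(rej - 0.05), 0.02)
  expect_equal(oneSampleSignedRank(rnorm(30))$method, "normal approximation")
})

test_that("BH adjustment reproduces hand-computed step-up values", {
  expect_equal(bhFdr(c(0.005, 0.05, 0.5)), c(0.015, 0.075, 0.5))
  expect_equal(bhFdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhFdr(0.37), 0.37)
  expect_error(bhFdr(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("BH output dominates input and preserves order", {
  set.seed(63)
  for (b in 1:20) {
    p <- runif(sample(3:20, 1))
    q <- bhFdr(p)
    expect_true(all(q >= p))
    expect_true(all(q <= 1))
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-15))
  }
})

test_that("partial Spearman reduces to classic Spearman without covariates", {
  set.seed(64)
  for (b in 1:20) {
    x <- rnorm(25); y <- rnorm(25)
    got <- partialSpearman(x, y)
    want <- oracleSpearman(x, y)
    expect_equal(got$estimate, want$estimate)
    expect_equal(got$p, want$p)
  }
  mono <- partialSpearman(1:20, exp(1:20 / 3))
  expect_equal(mono$estimate, 1)
})

test_that("partial Spearman holds the level and recovers injected correlation", {
  set.seed(65)
  B <- 1000
  rej <- 0
  for (b in seq_len(B)) {
    z <- matrix(rnorm(34 * 2), ncol = 2)
    x <- z[, 1] + rnorm(34)
    y <- z[, 1] - z[, 2] + rnorm(34)   # related only through covariates
    if (partialSpearman(x, y, z)$p < 0.05) rej <- rej + 1
  }
  expect_lt(abs(rej / B - 0.05), 0.025)
  # parameter recovery at rho = -0.4 given covariates
  rho <- -0.4
  est <- replicate(500, {
    z <- matrix(rnorm(34 * 2), ncol = 2)
    e <- MASS::mvrnorm(34, c(0, 0),
                       matrix(c(1, rho, rho, 1), 2))
    x <- 0.5 * z[, 1] + e[, 1]
    y <- -0.5 * z[, 2] + e[, 2]
    partialSpearman(x, y, z)$estimate
  })
  expect_lt(abs(mean(est) - (-0.4)), 0.05)
})

test_that("partial Spearman rejects degenerate inputs", {
  expect_error(partialSpearman(rep(1, 10), rnorm(10)), "constant")
  expect_error(partialSpearman(rnorm(4), rnorm(4),
                               matrix(rnorm(8), ncol = 2)), "covariates")
})

test_that("Mann-Whitney matches the exact hand example and null level", {
  res <- mannWhitney(1:3, 4:6)
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 0.1)
  expect_equal(res$method, "exact")
  expect_error(mannWhitney(numeric(0), 1:3), "empty")
  set.seed(66)
  ps <- replicate(500, mannWhitney(rnorm(30), rnorm(35))$p)
  # approximate p-values are mildly discrete; suppress the ks tie warning
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.001)
})

test_that("Fisher exact matches the hypergeometric hand example", {
  expect_equal(fisherExact(matrix(c(2, 0, 0, 2), 2))$p, 1 / 3)
  expect_error(fisherExact(matrix(0, 2, 2)), "all-zero")
  expect_error(fisherExact(matrix(c(1, 2, 3, -1), 2)), "non-negative")
})

test_that("every statistical routine returns p-values inside [0, 1]", {
  set.seed(67)
  for (b in 1:30) {
    n <- sample(8:40, 1)
    x <- cbind(rnorm(n))
    expect_true(all(rankFit(x, rnorm(n))@pval >= 0 &
                    rankFit(x, rnorm(n))@pval <= 1))
    p1 <- oneSampleSignedRank(rnorm(n))$p
    p2 <- mannWhitney(rnorm(n), rnorm(n))$p
    p3 <- partialSpearman(rnorm(n), rnorm(n), cbind(rnorm(n)))$p
    expect_true(all(c(p1, p2, p3) >= 0 & c(p1, p2, p3) <= 1))
  }
})
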