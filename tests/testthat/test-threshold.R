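toyWeighted <- function(vals) {
  # vals named by upper-tri edge "ij"
  w <- matrix(0, 4, 4)
  for (nm in names(vals)) {
    i <- as.integer(substr(nm, 1, 1)); j <- as.integer(substr(nm, 2, 2))
    w[i, j] <- w[j, i] <- vals[[nm]]
  }
  WeightedConnectome(w, LETTERS[1:4])
}

test_that("proportional thresholding keeps the k strongest edges", {
  wc <- toyWeighted(c("12" = 5, "13" = 4, "14" = 3, "23" = 2, "24" = 1,
                      "34" = 0.5))
  th <- thresholdProportional(wc, 0.5)
  w <- connWeights(th)
  expect_equal(w["A", "B"], 5, ignore_attr = TRUE)
  expect_equal(w["A", "C"], 4, ignore_attr = TRUE)
  expect_equal(w["A", "D"], 3, ignore_attr = TRUE)
  expect_equal(w["B", "C"] + w["B", "D"] + w["C", "D"], 0, ignore_attr = TRUE)
})

test_that("proportion 1 is the identity and bad proportions error", {
  wc <- toyWeighted(c("12" = 5, "13" = 4, "23" = 2))
  # at p = 1 with fewer positive weights than pairs, all are kept (warned)
  expect_warning(th1 <- thresholdProportional(wc, 1), "positive")
  expect_identical(th1@weights, wc@weights)
  full <- toyWeighted(c("12" = 5, "13" = 4, "14" = 3, "23" = 2, "24" = 1,
                        "34" = 0.5))
  expect_identical(thresholdProportional(full, 1)@weights, full@weights)
  expect_error(thresholdProportional(wc, 0), "proportion")
  expect_error(thresholdProportional(wc, 1.2), "proportion")
  zero <- WeightedConnectome(matrix(0, 3, 3), c("a", "b", "c"))
  expect_error(thresholdProportional(zero, 0.5), "all-zero")
})

test_that("ties at the cutoff break by row-major edge order", {
  # edges (1,4) and (2,3) tie at rank k = 3; row-major order keeps (1,4)
  wc <- toyWeighted(c("12" = 5, "13" = 4, "14" = 3, "23" = 3, "24" = 1,
                      "34" = 0.5))
  th <- thresholdProportional(wc, 0.5)
  w <- connWeights(th)
  expect_equal(sum(w[upper.tri(w)] > 0), 3)
  expect_true(w["A", "D"] > 0)
  expect_equal(w["B", "C"], 0, ignore_attr = TRUE)
})

test_that("fewer positive weights than k retains all with a warning", {
  wc <- toyWeighted(c("12" = 5, "13" = 4))
  expect_warning(th <- thresholdProportional(wc, 0.9), "positive")
  expect_equal(sum(connWeights(th) > 0) / 2, 2)
})

test_that("thresholding is scale invariant", {
  set.seed(21)
  w <- matrix(0, 10, 10); up <- upper.tri(w)
  w[up] <- runif(sum(up)); w <- w + t(w)
  wc <- WeightedConnectome(w, sprintf("r%d", 1:10))
  wc2 <- WeightedConnectome(w * 37.5, sprintf("r%d", 1:10))
  g1 <- binarize(thresholdProportional(wc, 0.2))
  g2 <- binarize(thresholdProportional(wc2, 0.2))
  expect_identical(adjacency(g1), adjacency(g2))
})

test_that("retained edges nest across increasing proportions (no ties)", {
  set.seed(22)
  w <- matrix(0, 12, 12); up <- upper.tri(w)
  w[up] <- runif(sum(up)); w <- w + t(w)
  wc <- WeightedConnectome(w, sprintf("r%d", 1:12))
  a1 <- adjacency(binarize(thresholdProportional(wc, 0.1)))
  a2 <- adjacency(binarize(thresholdProportional(wc, 0.3)))
  expect_true(all(a2[a1 == 1] == 1))
})

test_that("default thresholded density hits 20% within one-edge rounding", {
  set.seed(23)
  for (n in c(30, 61)) {
    w <- matrix(0, n, n); up <- upper.tri(w)
    w[up] <- runif(sum(up)); w <- w + t(w)
    wc <- WeightedConnectome(w, sprintf("r%d", 1:n))
    g <- binarize(thresholdProportional(wc, 0.2))
    expect_lt(abs(edgeDensity(g) - 0.2), 1 / (n * (n - 1) / 2) + 1e-12)
  }
})

test_that("the nonzero basis counts k against positive weights only", {
  # 4 positive of 6 possible edges; keep half of the positive ones
  wc <- toyWeighted(c("12" = 5, "13" = 4, "14" = 3, "23" = 2))
  th <- thresholdProportional(wc, 0.5, basis = "nonzero")
  expect_equal(sum(connWeights(th) > 0) / 2, 2)
})

test_that("binarize maps positive weights to edges and is idempotent", {
  wc <- toyWeighted(c("12" = 5, "13" = 4, "14" = 3))
  g <- binarize(wc)
  expect_equal(edgeDensity(g), 0.5)
  expect_equal(sum(adjacency(g)), 6)
  again <- binarize(WeightedConnectome(g@adjacency, g@labels))
  expect_identical(again@adjacency, g@adjacency)
  zero <- WeightedConnectome(matrix(0, 3, 3), c("a", "b", "c"))
  expect_equal(edgeDensity(binarize(zero)), 0)
})
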