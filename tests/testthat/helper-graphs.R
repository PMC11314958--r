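# toy graphs and independent brute-force oracles shared by the test files

toyGraph <- function(which) {
  m <- switch(which,
    k4 = { a <- matrix(1, 4, 4); diag(a) <- 0; a },
    p3 = { a <- matrix(0, 3, 3); a[1, 2] <- a[2, 3] <- 1; a + t(a) },
    p4 = { a <- matrix(0, 4, 4); a[1, 2] <- a[2, 3] <- a[3, 4] <- 1
           a + t(a) },
    star4 = { a <- matrix(0, 4, 4); a[1, 2:4] <- 1; a + t(a) },
    c5 = { a <- matrix(0, 5, 5)
           for (i in 1:5) { j <- i %% 5 + 1; a[i, j] <- a[j, i] <- 1 }; a },
    triangle = { a <- matrix(1, 3, 3); diag(a) <- 0; a },
    stop("unknown toy graph"))
  m
}

randomAdjacency <- function(n, p = 0.3) {
  a <- matrix(0, n, n)
  up <- upper.tri(a)
  a[up] <- rbinom(sum(up), 1, p)
  a + t(a)
}

# oracle 1: Floyd-Warshall all-pairs shortest paths
oracleFloydWarshall <- function(a) {
  n <- nrow(a)
  d <- ifelse(a > 0, 1, Inf)
  diag(d) <- 0
  for (k in seq_len(n))
    d <- pmin(d, outer(d[, k], d[k, ], "+"))
  d
}

# oracle 2: clustering by explicit triangle enumeration over node triples
oracleClustering <- function(a) {
  n <- nrow(a)
  vapply(seq_len(n), function(i) {
    nb <- which(a[i, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    t <- 0
    for (u in seq_len(k - 1))
      for (v in (u + 1):k)
        if (a[nb[u], nb[v]] > 0) t <- t + 1
    2 * t / (k * (k - 1))
  }, numeric(1))
}

# oracle 3: eigenvector centrality by plain power iteration; the shift by
# +I keeps the leading eigenvector but prevents oscillation on bipartite
# graphs (where |lambda_min| = lambda_max)
oraclePowerIteration <- function(a, iter = 100000, tol = 1e-13) {
  v <- rep(1, nrow(a))
  v <- v / sqrt(sum(v^2))
  for (i in seq_len(iter)) {
    w <- as.numeric(a %*% v) + v
    nw <- sqrt(sum(w^2))
    if (nw == 0) stop("power iteration collapsed")
    w <- w / nw
    if (max(abs(w - v)) < tol) return(w)
    v <- w
  }
  v
}

oracleGlobalEfficiency <- function(a) {
  d <- oracleFloydWarshall(a)
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv) / (nrow(a) * (nrow(a) - 1))
}

# random connected adjacency (rejection sampling on top of a spanning chain)
randomConnectedAdjacency <- function(n, p = 0.15) {
  a <- matrix(0, n, n)
  for (i in seq_len(n - 1)) a[i, i + 1] <- a[i + 1, i] <- 1
  up <- upper.tri(a)
  add <- rbinom(sum(up), 1, p)
  a[up] <- pmax(a[up], add)
  a[lower.tri(a)] <- t(a)[lower.tri(a)]
  a
}

# exact signed-rank two-sided p by enumerating all 2^n sign assignments
oracleSignedRankP <- function(values) {
  nz <- values[values != 0]
  n <- length(nz)
  r <- rank(abs(nz))
  v <- sum(r[nz > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- signs %*% r
  min(1, 2 * min(mean(vs <= v), mean(vs >= v)))
}

# textbook Spearman rho with t-based p
oracleSpearman <- function(x, y) {
  r <- cor(rank(x), rank(y))
  n <- length(x)
  tval <- r * sqrt((n - 2) / (1 - r^2))
  list(estimate = r, p = 2 * pt(-abs(tval), n - 2))
}

covariatesOf <- function(subjects)
  data.frame(age = subjects$age_at_death,
             sex = as.numeric(subjects$sex == "M"),
             pmd = subjects$postmortem_delay)
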