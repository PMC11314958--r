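# Rank-based statistical machinery: Jaeckel dispersion rank regression with
# Wilcoxon scores, exact signed-rank deviation test, BH-FDR, partial
# Spearman correlation, Mann-Whitney / Fisher demographics tests, Cohen d.

# Wilcoxon scores a(i) = sqrt(12) (i/(n+1) - 1/2), evaluated at (possibly
# tied, hence non-integer average) ranks
.wscores <- function(r, n) sqrt(12) * (r / (n + 1) - 0.5)

.dispersion <- function(beta, x, y) {
  e <- y - x %*% beta
  sum(.wscores(rank(e), length(e)) * e)
}

.dispersionGrad <- function(beta, x, y) {
  e <- y - x %*% beta
  -crossprod(x, .wscores(rank(e), length(e)))
}

# Koul-Sievers-McKean window estimator of the Wilcoxon scale parameter
# tau = 1 / (sqrt(12) integral f^2): density of the pairwise residual
# difference at zero, estimated with a shrinking window h = Q_delta / sqrt(n)
.ksmTau <- function(e, p, delta = if (length(e) / max(p, 1) > 5) 0.80
                                  else 0.95) {
  n <- length(e)
  d <- abs(outer(e, e, "-"))
  d <- sort(d[upper.tri(d)])
  if (p > 0 && length(d) > p) d <- d[-seq_len(p)]  # drop fit-forced zeros
  if (max(d) < .Machine$double.eps) return(0)      # degenerate exact fit
  h <- stats::quantile(d, delta, names = FALSE) / sqrt(n)
  frac <- mean(d <= h)
  if (frac == 0 || h == 0) {
    h <- min(d[d > 0])
    frac <- mean(d <= h)
  }
  sqrt(n / (n - p - 1)) * 2 * h / (sqrt(12) * frac)
}

#' Rank-based linear model fit (Jaeckel dispersion, Wilcoxon scores)
#'
#' Estimates slopes by minimizing Jaeckel's rank dispersion
#' \eqn{D(\beta) = \sum_i a(R(e_i)) e_i} with Wilcoxon scores
#' \eqn{a(i) = \sqrt{12}(i/(n+1) - 1/2)} and residuals
#' \eqn{e = y - X\beta}. D is convex and location-invariant, so the
#' intercept is estimated afterwards as the median of the residuals.
#' Standard errors are \eqn{\hat\tau \sqrt{(X_c'X_c)^{-1}}} with the
#' Koul-Sievers-McKean window estimate of the Wilcoxon scale parameter
#' \eqn{\tau}, and t tests use df = n - p - 1.
#'
#' Minimization runs BFGS from the least-squares start with the analytic
#' subgradient, capped at 500 iterations with relative tolerance 1e-8 on the
#' dispersion.
#'
#' @param x numeric n x p design matrix of predictors (no intercept column).
#' @param y numeric response vector of length n.
#' @return a [RankFit-class]
#' @examples
#' set.seed(1)
#' x <- cbind(rnorm(30))
#' fit <- rankFit(x, 2 * x[, 1] + 3)
#' coef(fit)  # ~2
#' @export
rankFit <- function(x, y) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  n <- length(y)
  p <- ncol(x)
  if (nrow(x) != n) stop("x and y dimensions disagree")
  if (n <= p + 1) stop("need n > p + 1 observations")
  xc <- scale(x, center = TRUE, scale = FALSE)
  if (qr(xc)$rank < p) stop("design matrix is rank deficient after centering")
  beta0 <- qr.coef(qr(xc), y - mean(y))
  opt <- stats::optim(beta0, .dispersion, .dispersionGrad, x = x, y = y,
                      method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-8))
  beta <- as.numeric(opt$par)
  e <- as.numeric(y - x %*% beta)
  intercept <- stats::median(e)
  tau <- .ksmTau(e, p)
  covb <- tau^2 * chol2inv(chol(crossprod(xc)))
  se <- sqrt(diag(covb))
  tstat <- ifelse(se > 0, beta / se, ifelse(beta == 0, 0, sign(beta) * Inf))
  df <- n - p - 1L
  pv <- 2 * stats::pt(-abs(tstat), df)
  cn <- colnames(x)
  if (is.null(cn)) cn <- sprintf("x%d", seq_len(p))
  new("RankFit",
      coefficients = structure(beta, names = cn), intercept = intercept,
      se = structure(se, names = cn), tstat = structure(tstat, names = cn),
      pval = structure(pv, names = cn), tauhat = tau, df = as.integer(df),
      residuals = e - intercept, converged = opt$convergence == 0L)
}

#' Slope estimates of a RankFit
#'
#' @param object a [RankFit-class]
#' @param ... ignored
#' @return named numeric vector of slope estimates (intercept excluded)
#' @importFrom stats coef
#' @export
setMethod("coef", "RankFit", function(object, ...) object@coefficients)

#' Cohen's d standardized mean difference
#'
#' (mean(b) - mean(a)) / pooled SD; with the case group as \code{b} the sign
#' convention is case minus control.
#'
#' @param a numeric vector (reference group, e.g. controls)
#' @param b numeric vector (comparison group, e.g. cases)
#' @return Cohen's d
#' @export
cohensD <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("each group needs at least 2 values")
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  if (sp2 == 0) stop("zero pooled SD: Cohen d is undefined")
  (mean(b) - mean(a)) / sqrt(sp2)
}

#' Covariate-adjusted group difference test
#'
#' Rank-based linear model of a per-subject measure on a case indicator plus
#' covariates (default age, sex, postmortem delay): the reported coefficient
#' and p-value are for the group indicator (case minus control, adjusted).
#' Cohen's d is computed on the raw values, unadjusted. Subjects with a
#' missing covariate or value are dropped (complete-case) with a message.
#'
#' @param values numeric per-subject measure.
#' @param group factor/character with exactly two levels; \code{caseLevel}
#'   is coded 1.
#' @param covariates data.frame or matrix of numeric covariates (may be NULL).
#' @param caseLevel value of \code{group} coding the case group; default "PD".
#' @return list with estimate, p, d, nControl, nCase, fit
#' @export
groupDifferenceTest <- function(values, group, covariates = NULL,
                                caseLevel = "PD") {
  group <- as.character(group)
  ok <- !is.na(values) & !is.na(group)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    ok <- ok & stats::complete.cases(covariates)
  }
  if (any(!ok))
    message("dropping ", sum(!ok), " subject(s) with missing data")
  values <- values[ok]
  group <- group[ok]
  g <- as.numeric(group == caseLevel)
  if (sum(g) < 3 || sum(1 - g) < 3) stop("each group needs at least 3 subjects")
  x <- cbind(group = g)
  if (!is.null(covariates)) {
    cv <- data.matrix(covariates[ok, , drop = FALSE])
    x <- cbind(x, cv)
  }
  fit <- rankFit(x, values)
  d <- cohensD(values[g == 0], values[g == 1])
  list(estimate = unname(coef(fit)["group"]), p = unname(fit@pval["group"]),
       d = d, nControl = sum(1 - g), nCase = sum(g), fit = fit)
}

# exact null distribution of the signed-rank statistic for given (possibly
# tied, average) ranks, via the generating function over all 2^n sign
# assignments; ranks are doubled so tied half-ranks become integers
.signedRankExactP <- function(v, r) {
  r2 <- as.integer(round(2 * r))
  counts <- 1          # counts[s + 1] = number of assignments with 2V = s
  for (ri in r2) {
    shifted <- c(numeric(ri), counts)
    counts <- c(counts, numeric(ri)) + shifted
  }
  tot <- sum(counts)   # 2^n
  s <- round(2 * v)
  pLe <- sum(counts[seq_len(s + 1)]) / tot
  pGe <- sum(counts[(s + 1):length(counts)]) / tot
  min(1, 2 * min(pLe, pGe))
}

#' One-sample Wilcoxon signed-rank test against zero
#'
#' Two-sided test that values are symmetric about zero. Exact zeros are
#' dropped; at least 5 nonzero values are required. For n <= 25 the exact
#' null distribution is used (computed by convolution over all sign
#' assignments, valid with tied average ranks); for larger n a normal
#' approximation with continuity and tie correction is used.
#'
#' @param values numeric vector.
#' @return list with statistic (V, sum of positive signed ranks), p, n
#'   (nonzero count), method
#' @export
oneSampleSignedRank <- function(values) {
  values <- values[!is.na(values)]
  nz <- values[values != 0]
  n <- length(nz)
  if (n == 0) stop("all values are zero")
  if (n < 5) stop("need at least 5 nonzero values")
  r <- rank(abs(nz))
  v <- sum(r[nz > 0])
  if (n <= 25) {
    p <- .signedRankExactP(v, r)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie^3 - tie) / 48
    z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sig2)
    if (v == mu) z <- 0
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation"
  }
  list(statistic = v, p = min(1, p), n = n, method = method)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with enforced monotonicity, capped at 1. Input
#' entries must lie in [0, 1].
#'
#' @param p numeric vector of p-values.
#' @return adjusted p-values, same length and order
#' @export
bhFdr <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Partial Spearman correlation with covariates
#'
#' Rank-transforms x, y, and each covariate (average ranks for ties),
#' residualizes the ranked x and y on the ranked covariates plus an
#' intercept by least squares, and returns the Pearson correlation of the
#' residuals. The p-value uses the t approximation with df = n - 2 - q
#' (q = number of covariates). With no covariates this reduces to the
#' classic Spearman rank correlation.
#'
#' @param x,y numeric vectors.
#' @param covariates data.frame/matrix of covariates, or NULL.
#' @return list with estimate (r_s), p, n, df
#' @export
partialSpearman <- function(x, y, covariates = NULL) {
  ok <- !is.na(x) & !is.na(y)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    ok <- ok & stats::complete.cases(covariates)
  }
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  q <- if (is.null(covariates)) 0L else ncol(covariates)
  if (n <= q + 2) stop("need n > number of covariates + 2")
  rx <- rank(x); ry <- rank(y)
  if (stats::var(rx) == 0) stop("x is constant after ranking")
  if (stats::var(ry) == 0) stop("y is constant after ranking")
  if (q > 0) {
    rc <- apply(data.matrix(covariates[ok, , drop = FALSE]), 2, rank)
    z <- cbind(1, rc)
    rx <- stats::lm.fit(z, rx)$residuals
    ry <- stats::lm.fit(z, ry)$residuals
    if (stats::var(rx) == 0 || stats::var(ry) == 0)
      stop("no rank variation left after residualizing on covariates")
  }
  r <- stats::cor(rx, ry)
  df <- n - 2 - q
  tval <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tval), df)
  list(estimate = r, p = min(1, p), n = n, df = df)
}

#' Mann-Whitney U test
#'
#' Two-sided two-sample rank test. Exact when the smaller group has at most
#' 8 observations and there are no ties across the pooled sample; otherwise
#' the normal approximation with tie correction and continuity correction.
#'
#' @param a,b numeric vectors.
#' @return list with statistic (U for a vs b), p, method
#' @export
mannWhitney <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) == 0 || length(b) == 0) stop("empty group")
  ex <- min(length(a), length(b)) <= 8 && !anyDuplicated(c(a, b))
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = ex, correct = TRUE))
  list(statistic = unname(wt$statistic), p = wt$p.value,
       method = if (ex) "exact" else "normal approximation")
}

#' Fisher exact test for a 2 x 2 table
#'
#' Two-sided by the point-probability rule (all tables at most as probable
#' as the observed one).
#'
#' @param tab 2 x 2 matrix of non-negative integer counts.
#' @return list with p
#' @export
fisherExact <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("need a 2 x 2 table")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers")
  if (sum(tab) == 0) stop("all-zero table")
  list(p = stats::fisher.test(tab)$p.value)
}
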