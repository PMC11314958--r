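#' @import methods
NULL

#' WeightedConnectome: a labelled, symmetric, non-negative connectivity matrix
#'
#' Container for a single subject's structural connectome: an n x n matrix of
#' non-negative connection weights (e.g. SIFT2-weighted streamline counts)
#' over n labelled grey-matter regions. The matrix must be symmetric (the
#' network is undirected), have an exactly zero diagonal (no self-connections)
#' and unique region labels.
#'
#' @slot labels character vector of n unique region labels.
#' @slot weights numeric n x n matrix of non-negative weights.
#'
#' @seealso [readConnectome()], [thresholdProportional()], [binarize()]
#' @export
setClass("WeightedConnectome",
  representation(labels = "character", weights = "matrix"))

setValidity("WeightedConnectome", function(object) {
  w <- object@weights
  lab <- object@labels
  n <- length(lab)
  msg <- character(0)
  if (!is.numeric(w)) msg <- c(msg, "weights must be numeric")
  if (nrow(w) != ncol(w)) msg <- c(msg, "weights must be square")
  if (nrow(w) != n) msg <- c(msg, "label count must match matrix dimension")
  if (n < 3) msg <- c(msg, "at least 3 regions are required")
  if (anyDuplicated(lab)) msg <- c(msg, "region labels must be unique")
  if (length(msg) == 0) {
    if (anyNA(w)) msg <- c(msg, "weights must not contain NA")
    else {
      if (any(w < 0)) msg <- c(msg, "weights must be non-negative")
      if (any(diag(w) != 0)) msg <- c(msg, "diagonal must be exactly zero")
      if (max(abs(w - t(w))) > 1e-9)
        msg <- c(msg, "weights must be symmetric within 1e-9")
    }
  }
  if (length(msg)) msg else TRUE
})

#' BinaryGraph: a thresholded, binarized undirected graph
#'
#' Adjacency representation of a connectome after proportional thresholding
#' and binarization: entries are 0/1, the diagonal is zero, and the stored
#' edge density equals the retained fraction of the n(n-1)/2 possible edges.
#'
#' @slot labels character vector of n unique region labels.
#' @slot adjacency numeric n x n matrix with entries in {0, 1}.
#' @slot density retained fraction of possible edges.
#'
#' @seealso [binarize()], [globalEfficiency()], [lesionNode()]
#' @export
setClass("BinaryGraph",
  representation(labels = "character", adjacency = "matrix",
                 density = "numeric"))

setValidity("BinaryGraph", function(object) {
  a <- object@adjacency
  n <- length(object@labels)
  msg <- character(0)
  if (nrow(a) != ncol(a) || nrow(a) != n)
    msg <- c(msg, "adjacency must be square and match label count")
  if (anyDuplicated(object@labels)) msg <- c(msg, "labels must be unique")
  if (length(msg) == 0) {
    if (!all(a %in% c(0, 1))) msg <- c(msg, "adjacency entries must be 0 or 1")
    else {
      if (any(diag(a) != 0)) msg <- c(msg, "diagonal must be zero")
      if (any(a != t(a))) msg <- c(msg, "adjacency must be symmetric")
      m <- sum(a[upper.tri(a)])
      dens <- if (n > 1) m / (n * (n - 1) / 2) else 0
      if (abs(object@density - dens) > 1e-12)
        msg <- c(msg, "stored density does not match edge count")
    }
  }
  if (length(msg)) msg else TRUE
})

#' RegionSet: analysis regions resolved to node indices
#'
#' Maps a set of named analysis regions of interest (by default the 8
#' right-hemisphere cortical ROIs sampled at autopsy) to node indices of a
#' connectome's label vector.
#'
#' @slot roiNames character vector of region-of-interest names.
#' @slot nodeIndices integer vector of matching node indices (1-based).
#' @slot hemisphere single string, fixed to "right" for the default table.
#'
#' @seealso [resolveRois()], [defaultRoiTable()]
#' @export
setClass("RegionSet",
  representation(roiNames = "character", nodeIndices = "integer",
                 hemisphere = "character"))

setValidity("RegionSet", function(object) {
  msg <- character(0)
  if (length(object@roiNames) != length(object@nodeIndices))
    msg <- c(msg, "roiNames and nodeIndices must have equal length")
  if (length(object@roiNames) < 1) msg <- c(msg, "at least one ROI required")
  if (anyDuplicated(object@roiNames)) msg <- c(msg, "ROI names must be unique")
  if (anyDuplicated(object@nodeIndices))
    msg <- c(msg, "node indices must be unique")
  if (any(object@nodeIndices < 1)) msg <- c(msg, "indices must be >= 1")
  if (length(msg)) msg else TRUE
})

#' RankFit: a fitted rank-based linear model
#'
#' Result of minimizing Jaeckel's rank dispersion with Wilcoxon scores. The
#' intercept is estimated separately as the median of the residuals, and the
#' coefficient standard errors use the Koul-Sievers-McKean window estimate of
#' the Wilcoxon scale parameter tau.
#'
#' @slot coefficients slope estimates (no intercept).
#' @slot intercept median-of-residuals intercept.
#' @slot se standard errors of the slopes.
#' @slot tstat t statistics (df = n - p - 1).
#' @slot pval two-sided p-values.
#' @slot tauhat Wilcoxon scale estimate.
#' @slot df residual degrees of freedom.
#' @slot residuals response minus fitted values (including intercept).
#' @slot converged logical optimizer convergence flag.
#'
#' @seealso [rankFit()]
#' @export
setClass("RankFit",
  representation(coefficients = "numeric", intercept = "numeric",
                 se = "numeric", tstat = "numeric", pval = "numeric",
                 tauhat = "numeric", df = "integer", residuals = "numeric",
                 converged = "logical"))

setValidity("RankFit", function(object) {
  p <- length(object@coefficients)
  msg <- character(0)
  if (length(object@se) != p || length(object@tstat) != p ||
      length(object@pval) != p)
    msg <- c(msg, "coefficient vectors must have equal length")
  if (any(object@pval < 0 | object@pval > 1, na.rm = TRUE))
    msg <- c(msg, "p-values must lie in [0, 1]")
  if (object@df <= 0) msg <- c(msg, "residual df must be positive")
  if (length(msg)) msg else TRUE
})

setMethod("show", "WeightedConnectome", function(object) {
  n <- length(object@labels)
  w <- object@weights
  pos <- sum(w[upper.tri(w)] > 0)
  cat("WeightedConnectome with", n, "regions\n")
  cat("  positive connections:", pos, "of", n * (n - 1) / 2, "\n")
  cat("  weight range: [", format(min(w)), ",", format(max(w)), "]\n")
  cat("  labels:", paste(utils::head(object@labels, 4), collapse = ", "),
      if (n > 4) "..." else "", "\n")
})

setMethod("show", "BinaryGraph", function(object) {
  n <- length(object@labels)
  cat("BinaryGraph with", n, "nodes,",
      sum(object@adjacency[upper.tri(object@adjacency)]), "edges\n")
  cat("  density:", format(object@density, digits = 4), "\n")
})

setMethod("show", "RegionSet", function(object) {
  cat("RegionSet (", object@hemisphere, " hemisphere), ",
      length(object@roiNames), " regions\n", sep = "")
  for (i in seq_along(object@roiNames))
    cat("  ", object@roiNames[i], "-> node", object@nodeIndices[i], "\n")
})

setMethod("show", "RankFit", function(object) {
  cat("Rank-based linear fit (Wilcoxon scores)\n")
  cat("  intercept:", format(object@intercept, digits = 4), "\n")
  tab <- data.frame(estimate = object@coefficients, se = object@se,
                    t = object@tstat, p = object@pval)
  print(format(tab, digits = 4))
  cat("  tau-hat:", format(object@tauhat, digits = 4),
      " df:", object@df,
      " converged:", object@converged, "\n")
})

#' @describeIn WeightedConnectome-class number of nodes
#' @param x a WeightedConnectome, BinaryGraph or RegionSet
#' @export
nNodes <- function(x) {
  if (is(x, "WeightedConnectome")) length(x@labels)
  else if (is(x, "BinaryGraph")) length(x@labels)
  else stop("nNodes() expects a WeightedConnectome or BinaryGraph")
}

#' Region labels of a connectome object
#' @param x a WeightedConnectome or BinaryGraph
#' @return character vector of region labels
#' @export
regionLabels <- function(x) {
  if (is(x, "WeightedConnectome") || is(x, "BinaryGraph")) x@labels
  else if (is(x, "RegionSet")) x@roiNames
  else stop("regionLabels() expects a connectome object")
}

#' Weight matrix of a WeightedConnectome
#' @param x a WeightedConnectome
#' @return numeric matrix of weights, with label dimnames
#' @export
connWeights <- function(x) {
  stopifnot(is(x, "WeightedConnectome"))
  w <- x@weights
  dimnames(w) <- list(x@labels, x@labels)
  w
}

#' Adjacency matrix of a BinaryGraph
#' @param x a BinaryGraph
#' @return numeric 0/1 matrix with label dimnames
#' @export
adjacency <- function(x) {
  stopifnot(is(x, "BinaryGraph"))
  a <- x@adjacency
  dimnames(a) <- list(x@labels, x@labels)
  a
}

#' Edge density of a BinaryGraph
#' @param x a BinaryGraph
#' @return retained fraction of possible edges
#' @export
edgeDensity <- function(x) {
  stopifnot(is(x, "BinaryGraph"))
  x@density
}

#' Node indices of a RegionSet
#' @param x a RegionSet
#' @return named integer vector (names are ROI names)
#' @export
nodeIndices <- function(x) {
  stopifnot(is(x, "RegionSet"))
  structure(x@nodeIndices, names = x@roiNames)
}

#' Construct a WeightedConnectome
#'
#' @param weights numeric symmetric non-negative matrix with zero diagonal.
#' @param labels character vector of unique region labels; defaults to the
#'   matrix rownames.
#' @return a validated [WeightedConnectome-class] object
#' @export
WeightedConnectome <- function(weights, labels = rownames(weights)) {
  if (is.null(labels)) stop("region labels are required")
  weights <- as.matrix(weights)
  dimnames(weights) <- NULL
  new("WeightedConnectome", labels = as.character(labels), weights = weights)
}

#' Construct a BinaryGraph from a 0/1 adjacency matrix
#'
#' @param adjacency numeric symmetric 0/1 matrix with zero diagonal.
#' @param labels character vector of unique node labels; defaults to the
#'   matrix rownames, or "node_i" if absent.
#' @return a validated [BinaryGraph-class] object
#' @export
BinaryGraph <- function(adjacency, labels = rownames(adjacency)) {
  adjacency <- as.matrix(adjacency)
  n <- nrow(adjacency)
  if (is.null(labels)) labels <- sprintf("node_%d", seq_len(n))
  dimnames(adjacency) <- NULL
  storage.mode(adjacency) <- "double"
  dens <- if (n > 1) sum(adjacency[upper.tri(adjacency)]) / (n * (n - 1) / 2)
          else 0
  new("BinaryGraph", labels = as.character(labels), adjacency = adjacency,
      density = dens)
}
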