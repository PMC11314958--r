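# Proportional thresholding and binarization.

# round half away from zero, as in the common connectomics toolboxes
.roundHalfUp <- function(x) floor(x + 0.5)

# upper-triangle edges in row-major order: (1,2),(1,3),...,(1,n),(2,3),...
.edgeIndex <- function(n) {
  i <- rep.int(seq_len(n - 1), times = (n - 1):1)
  j <- sequence((n - 1):1, from = 2:n)
  cbind(i, j)
}

#' Proportional thresholding of a weighted connectome
#'
#' Keeps the k strongest positive connections, where k = round(proportion *
#' n(n-1)/2) (half away from zero) of the possible edges (default basis), or
#' of the nonzero edges with \code{basis = "nonzero"}. All other weights are
#' set to zero; the result stays symmetric. Ties at the retention cutoff are
#' broken deterministically by row-major edge order (smaller row, then
#' smaller column, first). If fewer than k positive weights exist, all
#' positive weights are retained with a warning.
#'
#' @param x a [WeightedConnectome-class]
#' @param proportion fraction of edges to keep, in (0, 1]; default 0.20.
#' @param basis "possible" (default) counts k against all n(n-1)/2 node
#'   pairs; "nonzero" counts against the positive-weight pairs only.
#' @return a thresholded [WeightedConnectome-class]
#' @examples
#' w <- matrix(0, 4, 4); w[1, 2] <- 5; w[1, 3] <- 4; w[1, 4] <- 3
#' w[2, 3] <- 2; w[2, 4] <- 1; w[3, 4] <- 0.5; w <- w + t(w)
#' wc <- WeightedConnectome(w, LETTERS[1:4])
#' connWeights(thresholdProportional(wc, 0.5))
#' @export
thresholdProportional <- function(x, proportion = 0.20,
                                  basis = c("possible", "nonzero")) {
  stopifnot(is(x, "WeightedConnectome"))
  basis <- match.arg(basis)
  if (!is.numeric(proportion) || length(proportion) != 1 ||
      proportion <= 0 || proportion > 1)
    stop("proportion must lie in (0, 1]")
  w <- x@weights
  n <- nrow(w)
  idx <- .edgeIndex(n)
  ew <- w[idx]
  npos <- sum(ew > 0)
  if (npos == 0) stop("all-zero connectivity matrix cannot be thresholded")
  m <- if (basis == "possible") nrow(idx) else npos
  k <- .roundHalfUp(proportion * m)
  if (k > npos) {
    warning("only ", npos, " positive weights available; keeping all ",
            "(requested ", k, ")")
    k <- npos
  }
  # weight descending, then row-major edge order ascending
  keep <- order(-ew, seq_along(ew))[seq_len(k)]
  out <- matrix(0, n, n)
  ki <- idx[keep, , drop = FALSE]
  out[ki] <- ew[keep]
  out[ki[, c(2, 1), drop = FALSE]] <- ew[keep]
  WeightedConnectome(out, x@labels)
}

#' Binarize a weighted connectome
#'
#' Every strictly positive weight becomes an edge. The retained edge density
#' is stored on the result.
#'
#' @param x a [WeightedConnectome-class]
#' @return a [BinaryGraph-class]
#' @export
binarize <- function(x) {
  stopifnot(is(x, "WeightedConnectome"))
  BinaryGraph((x@weights > 0) + 0, x@labels)
}
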