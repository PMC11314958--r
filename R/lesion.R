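# Virtual single-node failure and the resilience statistic dGE.

#' Remove one node from a binary graph
#'
#' Virtual lesioning by deletion: returns an (n-1)-node graph with the
#' node's row and column removed and labels updated. The input is not
#' modified. With \code{mode = "zero"} the node count is kept and the node's
#' row and column are set to zero instead (sensitivity variant; the lesioned
#' node then contributes permanently unreachable pairs).
#'
#' @param g a [BinaryGraph-class]
#' @param node node index (1-based) or node label
#' @param mode "delete" (default) or "zero"
#' @return a [BinaryGraph-class]
#' @export
lesionNode <- function(g, node, mode = c("delete", "zero")) {
  stopifnot(is(g, "BinaryGraph"))
  mode <- match.arg(mode)
  n <- length(g@labels)
  if (is.character(node)) {
    idx <- match(node, g@labels)
    if (is.na(idx)) stop("unknown node label: ", node)
    node <- idx
  }
  if (!is.numeric(node) || length(node) != 1 || node < 1 || node > n ||
      node != as.integer(node))
    stop("node index out of range [1, ", n, "]")
  a <- g@adjacency
  if (mode == "delete") {
    BinaryGraph(a[-node, -node, drop = FALSE], g@labels[-node])
  } else {
    a[node, ] <- 0
    a[, node] <- 0
    BinaryGraph(a, g@labels)
  }
}

#' Change in global efficiency after single-node failure
#'
#' The resilience statistic dGE = GE_lesion - GE: global efficiency of the
#' graph after removing one node, minus global efficiency of the intact
#' graph. Values near zero indicate high resilience to that node's failure;
#' the statistic can be positive when an isolated or poorly connected node
#' is removed (the unreachable-pair mass shrinks).
#'
#' In the default "delete" mode GE_lesion is averaged over the
#' (n-1)(n-2) ordered pairs of the remaining nodes; in "zero" mode the node
#' stays in the graph with all connections masked, so its 2(n-1) pairs count
#' as unreachable.
#'
#' @param g a [BinaryGraph-class] with n >= 3
#' @param node node index or label to remove
#' @param mode "delete" (default) or "zero"
#' @return the dGE value (dimensionless)
#' @examples
#' star <- matrix(0, 4, 4); star[1, 2:4] <- 1; star <- star + t(star)
#' deltaGlobalEfficiency(BinaryGraph(star), 1)  # -0.75
#' @export
deltaGlobalEfficiency <- function(g, node, mode = c("delete", "zero")) {
  stopifnot(is(g, "BinaryGraph"))
  if (length(g@labels) < 3) stop("need at least 3 nodes to lesion")
  mode <- match.arg(mode)
  .ge(lesionNode(g, node, mode)@adjacency) - .ge(g@adjacency)
}

#' Resilience profile over a set of regions
#'
#' dGE for each ROI of a [RegionSet-class], with every lesion applied
#' independently to the intact graph (lesions are not cumulative).
#'
#' @param g a [BinaryGraph-class]
#' @param rois a [RegionSet-class] whose indices are valid for \code{g}
#' @param mode "delete" (default) or "zero"
#' @return named numeric vector of dGE values (names are ROI names)
#' @export
resilienceProfile <- function(g, rois, mode = c("delete", "zero")) {
  stopifnot(is(g, "BinaryGraph"), is(rois, "RegionSet"))
  mode <- match.arg(mode)
  if (any(rois@nodeIndices > length(g@labels)))
    stop("RegionSet index exceeds graph size")
  geIntact <- .ge(g@adjacency)
  out <- vapply(rois@nodeIndices, function(i)
    .ge(lesionNode(g, i, mode)@adjacency) - geIntact, numeric(1))
  names(out) <- rois@roiNames
  out
}
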