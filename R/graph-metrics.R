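# Binary undirected graph measures, implemented from scratch on the
# adjacency matrix. Workhorse functions operate on a plain 0/1 matrix; the
# exported functions accept a BinaryGraph or a bare adjacency matrix.

.asAdj <- function(g) {
  if (is(g, "BinaryGraph")) return(g@adjacency)
  if (is.matrix(g)) {
    if (!all(g %in% c(0, 1))) stop("adjacency entries must be 0 or 1")
    a <- g
    dimnames(a) <- NULL
    storage.mode(a) <- "double"
    return(a)
  }
  stop("expected a BinaryGraph or 0/1 matrix")
}

# All-pairs hop counts by simultaneous breadth-first search: the frontier of
# every source is advanced in lock step with one boolean matrix product per
# hop level.
.spl <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  frontier <- a > 0
  reached <- frontier
  diag(reached) <- TRUE
  d[frontier] <- 1
  level <- 1
  while (any(frontier)) {
    nxt <- ((frontier + 0) %*% a) > 0
    frontier <- nxt & !reached
    if (!any(frontier)) break
    level <- level + 1
    d[frontier] <- level
    reached <- reached | frontier
  }
  d
}

.ge <- function(a) {
  n <- nrow(a)
  if (n < 2) stop("global efficiency needs at least 2 nodes")
  d <- .spl(a)
  inv <- 1 / d          # 1/Inf = 0 for unreachable pairs
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

.cc <- function(a) {
  k <- rowSums(a)
  t2 <- diag(a %*% a %*% a)   # 2 * triangles through each node
  cc <- ifelse(k < 2, 0, t2 / (k * (k - 1)))
  as.numeric(cc)
}

# connected-component id per node, from the BFS reachability matrix
.components <- function(a) {
  reach <- is.finite(.spl(a))
  comp <- integer(nrow(a))
  cid <- 0
  for (i in seq_len(nrow(a))) {
    if (comp[i] == 0) {
      cid <- cid + 1
      comp[reach[i, ]] <- cid
    }
  }
  comp
}

.ec <- function(a, norm = c("unit", "max")) {
  norm <- match.arg(norm)
  n <- nrow(a)
  if (sum(a) == 0) stop("eigenvector centrality is undefined on an edgeless graph")
  es <- eigen(a, symmetric = TRUE)
  lam <- es$values
  v <- es$vectors[, 1]
  if (v[which.max(abs(v))] < 0) v <- -v
  degenerate <- sum(lam > lam[1] - 1e-10) > 1
  if (degenerate || min(v) < -1e-8) {
    # The leading eigenvalue of a connected graph is simple
    # (Perron-Frobenius), so a degenerate leading eigenvalue means tied
    # disconnected components. Deterministic resolution: take the Perron
    # vector of the tied component that contains the smallest node index,
    # zero elsewhere.
    message("degenerate leading eigenvalue; localizing on the ",
            "smallest-index tied component")
    comp <- .components(a)
    lead <- vapply(unique(comp), function(cid) {
      sub <- a[comp == cid, comp == cid, drop = FALSE]
      if (nrow(sub) == 1) 0 else eigen(sub, symmetric = TRUE,
                                       only.values = TRUE)$values[1]
    }, numeric(1))
    names(lead) <- unique(comp)
    tied <- as.integer(names(lead)[lead > max(lead) - 1e-10])
    pick <- tied[which.min(vapply(tied, function(cid) min(which(comp == cid)),
                                  numeric(1)))]
    v <- numeric(n)
    sub <- a[comp == pick, comp == pick, drop = FALSE]
    v[comp == pick] <- abs(eigen(sub, symmetric = TRUE)$vectors[, 1])
  }
  v[v < 0 & v > -1e-8] <- 0
  v <- abs(v)
  if (norm == "unit") v / sqrt(sum(v^2)) else v / max(v)
}

#' Shortest path lengths (hop counts) between all node pairs
#'
#' Breadth-first search from every node of a binary undirected graph.
#' Unreachable pairs have distance Inf.
#'
#' @param g a [BinaryGraph-class] or 0/1 adjacency matrix
#' @return symmetric numeric matrix of hop counts, zero diagonal
#' @export
shortestPathLengths <- function(g) .spl(.asAdj(g))

#' Global efficiency of a binary graph
#'
#' Mean inverse shortest path length over all ordered node pairs,
#' \eqn{GE = \frac{1}{n(n-1)} \sum_{i \ne j} 1/d_{ij}}, with 1/Inf taken as
#' 0 for disconnected pairs. Lies in [0, 1]; equals 1 exactly for a complete
#' graph.
#'
#' @param g a [BinaryGraph-class] or 0/1 adjacency matrix with n >= 2
#' @return global efficiency in [0, 1]
#' @examples
#' k4 <- matrix(1, 4, 4); diag(k4) <- 0
#' globalEfficiency(k4)  # 1
#' @export
globalEfficiency <- function(g) .ge(.asAdj(g))

#' Nodal clustering coefficients
#'
#' Fraction of closed triangles around each node:
#' \eqn{cc_i = 2 t_i / (k_i (k_i - 1))} with \eqn{t_i} the triangle count
#' through node i and \eqn{k_i} its degree; defined as 0 for degree < 2.
#'
#' @param g a [BinaryGraph-class] or 0/1 adjacency matrix
#' @return numeric vector of per-node clustering coefficients in [0, 1]
#' @export
nodalClustering <- function(g) .cc(.asAdj(g))

#' Mean clustering coefficient
#'
#' Unweighted mean of [nodalClustering()] over all nodes (degree < 2 nodes
#' contribute 0).
#'
#' @param g a [BinaryGraph-class] or 0/1 adjacency matrix
#' @return mean clustering coefficient in [0, 1]
#' @export
meanClustering <- function(g) mean(.cc(.asAdj(g)))

#' Eigenvector centrality
#'
#' Entry-wise non-negative leading eigenvector of the adjacency matrix,
#' computed by dense symmetric eigendecomposition and normalized to unit
#' Euclidean norm (or unit maximum with \code{norm = "max"}). On a
#' disconnected graph the leading eigenvector localizes on the component
#' with the largest spectral radius; a degenerate leading eigenvalue is
#' resolved deterministically (see Details in the package vignette).
#'
#' @param g a [BinaryGraph-class] or 0/1 adjacency matrix with >= 1 edge
#' @param norm "unit" (Euclidean norm 1, default) or "max" (largest entry 1)
#' @return numeric vector of non-negative centralities
#' @examples
#' star <- matrix(0, 4, 4); star[1, 2:4] <- 1; star <- star + t(star)
#' eigenvectorCentrality(star)  # center sqrt(1/2), leaves sqrt(1/6)
#' @export
eigenvectorCentrality <- function(g, norm = c("unit", "max"))
  .ec(.asAdj(g), match.arg(norm))
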