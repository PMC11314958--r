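#' Read a connectivity matrix from a TSV file
#'
#' Expects a tab-separated file whose first row holds the n region labels and
#' whose following n rows hold the n x n numeric weight matrix. Small
#' asymmetries (below 1e-6 in absolute value, typical of tractography export
#' round-off) are removed by averaging the matrix with its transpose; larger
#' asymmetries are an error, as are negative weights and duplicate labels.
#'
#' @param path path to the TSV file.
#' @param expectedN optional integer; error if the matrix is not expectedN x
#'   expectedN.
#' @return a [WeightedConnectome-class]
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' m <- matrix(c(0, 2, 0, 2, 0, 1, 0, 1, 0), 3,
#'             dimnames = list(NULL, c("A", "B", "C")))
#' writeConnectome(WeightedConnectome(m, c("A", "B", "C")), f)
#' readConnectome(f)
#' @export
readConnectome <- function(path, expectedN = NULL) {
  if (!file.exists(path)) stop("connectome file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 2) stop("malformed connectome file: ", path)
  labels <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  n <- length(labels)
  if (length(lines) != n + 1)
    stop("non-square input: ", n, " labels but ", length(lines) - 1,
         " data rows in ", path)
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  if (any(lengths(rows) != n))
    stop("non-square input: a data row of ", path,
         " does not have ", n, " fields")
  w <- matrix(as.numeric(unlist(rows)), nrow = n, byrow = TRUE)
  if (anyNA(w)) stop("non-numeric entries in ", path)
  if (!is.null(expectedN) && n != expectedN)
    stop("matrix is ", n, " x ", n, " but expected ", expectedN, " x ",
         expectedN, ": ", path)
  if (anyDuplicated(labels)) stop("duplicate region labels in ", path)
  if (any(w < 0)) stop("negative weight in ", path)
  asym <- max(abs(w - t(w)))
  if (asym >= 1e-6)
    stop("matrix asymmetry ", format(asym), " >= 1e-6 in ", path)
  if (asym > 0) w <- (w + t(w)) / 2
  diag(w) <- 0
  WeightedConnectome(w, labels)
}

#' Write a connectivity matrix to a TSV file
#'
#' Inverse of [readConnectome()]: the first line holds the labels and the
#' following n lines the weight rows. Weights are printed with the "%.17g"
#' format, so a write/read round trip reproduces the matrix bit for bit.
#'
#' @param x a [WeightedConnectome-class]
#' @param path output file path
#' @return invisibly, the path
#' @export
writeConnectome <- function(x, path) {
  stopifnot(is(x, "WeightedConnectome"))
  w <- x@weights
  body <- vapply(seq_len(nrow(w)), function(i)
    paste(sprintf("%.17g", w[i, ]), collapse = "\t"), character(1))
  writeLines(c(paste(x@labels, collapse = "\t"), body), path)
  invisible(path)
}

#' The default analysis-ROI table
#'
#' Two-column table (roi_name, atlas_label) mapping the 8 right-hemisphere
#' cortical regions sampled at autopsy (superior frontal gyrus, anterior and
#' posterior cingulate gyrus, dorsal anterior insula, middle temporal gyrus,
#' entorhinal cortex, parahippocampal gyrus, fusiform gyrus) to the atlas
#' labels used by the synthetic node-label table.
#'
#' @return data.frame with columns roi_name and atlas_label
#' @export
defaultRoiTable <- function() {
  path <- system.file("extdata", "roi_table.csv", package = "connectolesion",
                      mustWork = TRUE)
  readRoiTable(path)
}

#' Read a two-column ROI table
#'
#' @param path CSV file with header columns roi_name, atlas_label
#' @return data.frame with columns roi_name and atlas_label
#' @export
readRoiTable <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("roi_name", "atlas_label") %in% names(tab)))
    stop("ROI table must have columns roi_name and atlas_label: ", path)
  tab[, c("roi_name", "atlas_label")]
}

#' Resolve analysis ROIs to node indices
#'
#' Looks every atlas label of the ROI table up in a connectome's label vector
#' and returns the matching node indices. A label that is absent from, or
#' duplicated in, the connectome is an error.
#'
#' @param labels character vector of connectome region labels.
#' @param roiTable data.frame with columns roi_name and atlas_label; defaults
#'   to [defaultRoiTable()].
#' @param hemisphere annotation string stored on the result.
#' @return a [RegionSet-class]
#' @export
resolveRois <- function(labels, roiTable = defaultRoiTable(),
                        hemisphere = "right") {
  stopifnot(is.character(labels))
  idx <- integer(nrow(roiTable))
  for (i in seq_len(nrow(roiTable))) {
    hit <- which(labels == roiTable$atlas_label[i])
    if (length(hit) == 0)
      stop("ROI label not found in connectome: ", roiTable$atlas_label[i])
    if (length(hit) > 1)
      stop("ROI label is ambiguous in connectome: ", roiTable$atlas_label[i])
    idx[i] <- hit
  }
  new("RegionSet", roiNames = roiTable$roi_name, nodeIndices = idx,
      hemisphere = hemisphere)
}
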