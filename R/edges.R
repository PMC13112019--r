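# Edge-index convention and matrix <-> edge-vector conversion.
#
# A single convention is used everywhere in the package: edges enumerate the
# strict upper triangle of the N x N connectivity matrix in row-major order,
# i.e. (1,2), (1,3), ..., (1,N), (2,3), ..., (N-1,N) in R's 1-based region
# indices. File exports additionally carry 0-based (i, j) columns so that the
# on-disk convention is explicit and language-neutral.

#' Number of edges of an N-region connectome
#'
#' @param n_regions number of regions.
#' @return `n_regions * (n_regions - 1) / 2`.
#' @examples
#' n_edges(116) # 6670
#' @export
n_edges <- function(n_regions) {
  stopifnot(n_regions >= 2)
  as.integer(n_regions * (n_regions - 1) / 2)
}

#' Edge index table for an N-region connectome
#'
#' Enumerates the strict upper triangle in row-major order. Region indices
#' are 1-based; the exported file format uses the same ordering with
#' 0-based indices.
#'
#' @param n_regions number of regions.
#' @return data.frame with columns `edge` (1..E), `i`, `j` (1-based, i < j).
#' @export
edge_index <- function(n_regions) {
  stopifnot(n_regions >= 2)
  i <- rep.int(seq_len(n_regions - 1), times = (n_regions - 1):1)
  j <- sequence((n_regions - 1):1) + i
  data.frame(edge = seq_along(i), i = i, j = j)
}

#' Vectorize a symmetric connectivity matrix
#'
#' Extracts the strict upper triangle in row-major order, the package-wide
#' edge convention. A 116-region matrix yields a length-6670 vector.
#'
#' @param m symmetric numeric matrix (zero diagonal expected).
#' @param tol asymmetry tolerance; larger discrepancies are an error.
#' @return numeric vector of length `N(N-1)/2`.
#' @seealso [devectorize()]
#' @export
vectorize <- function(m, tol = 1e-10) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (max(abs(m - t(m))) > tol) {
    stop("matrix is asymmetric beyond tolerance ", format(tol))
  }
  t(m)[lower.tri(m)]
}

#' Rebuild a symmetric matrix from an edge vector
#'
#' Inverse of [vectorize()]: fills the strict upper triangle in row-major
#' order, mirrors it, and sets the diagonal to zero.
#'
#' @param v numeric edge vector of length `N(N-1)/2`.
#' @param n_regions number of regions N.
#' @return symmetric `N x N` matrix with zero diagonal.
#' @export
devectorize <- function(v, n_regions) {
  e <- n_edges(n_regions)
  if (length(v) != e) {
    stop("edge vector has length ", length(v), ", expected ", e,
         " for ", n_regions, " regions")
  }
  m <- matrix(0, n_regions, n_regions)
  m[lower.tri(m)] <- v   # column-major lower triangle == row-major upper
  m <- t(m)
  m + t(m)
}

#' Edges incident to a node
#'
#' @param edges integer vector of edge indices (1-based).
#' @param node region index (1-based).
#' @param idx edge index table from [edge_index()].
#' @return subset of `edges` touching `node`.
#' @keywords internal
incident_edges <- function(edges, node, idx) {
  sub <- idx[edges, , drop = FALSE]
  edges[sub$i == node | sub$j == node]
}
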