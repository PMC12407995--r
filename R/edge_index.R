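#' Edge index for component pairs
#'
#' Maps unordered component pairs (i, j), i < j, to flat edge indices and
#' back. The ordering is row-major over the upper triangle: (1,2), (1,3),
#' ..., (1,C), (2,3), ..., (C-1,C). All modules and file outputs use this
#' ordering; components and edges are 1-based throughout. For C = 53
#' components there are C(C-1)/2 = 1378 edges, one per connectivity feature.
#'
#' @param n_components number of components C (>= 2).
#' @return an object of class `edge_index` with fields `n_components`,
#'   `n_edges`, and the component vectors `i`, `j` for each flat index.
#' @examples
#' idx <- edge_index(53)
#' idx$n_edges            # 1378
#' edge_of(2, 1, idx)     # symmetric in its arguments
#' pair_of(1378, idx)     # c(52, 53)
#' @export
edge_index <- function(n_components) {
  .stop_if(!.is_count(n_components) || n_components < 2,
           "n_components must be a single integer >= 2")
  C <- as.integer(n_components)
  i <- rep.int(seq_len(C - 1L), times = (C - 1L):1L)
  j <- unlist(lapply(seq_len(C - 1L), function(a) (a + 1L):C),
              use.names = FALSE)
  structure(
    list(n_components = C, n_edges = as.integer(C * (C - 1L) / 2L),
         i = i, j = j),
    class = "edge_index"
  )
}

#' @export
print.edge_index <- function(x, ...) {
  cat(sprintf("<edge_index> %d components, %d edges (row-major upper triangle)\n",
              x$n_components, x$n_edges))
  invisible(x)
}

#' Flat edge index of a component pair
#'
#' Vectorized over `i` and `j`; symmetric, so `edge_of(i, j, idx)` equals
#' `edge_of(j, i, idx)`. Self-pairs are an error (the connectivity matrix
#' diagonal is not a feature).
#'
#' @param i,j component indices in 1..C.
#' @param idx an [edge_index()].
#' @return integer flat edge indices in 1..C(C-1)/2.
#' @export
edge_of <- function(i, j, idx) {
  .stop_if(!inherits(idx, "edge_index"), "idx must be an edge_index")
  C <- idx$n_components
  .stop_if(any(i < 1 | i > C | j < 1 | j > C | i != round(i) | j != round(j)),
           "component indices must be integers in 1..", C)
  .stop_if(any(i == j), "self-edges (i == j) are not indexed")
  lo <- pmin(i, j)
  hi <- pmax(i, j)
  as.integer((lo - 1) * (2 * C - lo) / 2 + (hi - lo))
}

#' Component pair of a flat edge index
#'
#' Inverse of [edge_of()]. Vectorized over `k`.
#'
#' @param k flat edge indices.
#' @param idx an [edge_index()].
#' @return integer matrix with columns `i`, `j` (i < j).
#' @export
pair_of <- function(k, idx) {
  .stop_if(!inherits(idx, "edge_index"), "idx must be an edge_index")
  .stop_if(any(k < 1 | k > idx$n_edges | k != round(k)),
           "edge indices must be integers in 1..", idx$n_edges)
  cbind(i = idx$i[k], j = idx$j[k])
}

#' Canonical edge column names
#'
#' `e_<i>_<j>` with 1-based component labels, in flat-index order; used for
#' all edge-table file outputs.
#'
#' @param idx an [edge_index()].
#' @return character vector of length `idx$n_edges`.
#' @export
edge_names <- function(idx) {
  .stop_if(!inherits(idx, "edge_index"), "idx must be an edge_index")
  sprintf("e_%d_%d", idx$i, idx$j)
}
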