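#' Static functional network connectivity matrix
#'
#' Pearson correlation between every pair of component time courses:
#' for columns x1, x2 the entry is the centered cross-product divided by the
#' product of centered norms, so values lie in \[-1, 1\] and measure the
#' strength of the linear relationship. The result is symmetric with unit
#' diagonal. Constant columns have no defined correlation: their whole
#' row/column is set to `NA` (an explicit undefined marker, never silently
#' zero) and reported in a warning.
#'
#' Correlations are used raw; set `fisher_z = TRUE` to apply the
#' variance-stabilizing atanh transform favored by some toolboxes.
#'
#' @param tc a `timecourse` object or a T x C numeric matrix (T >= 3).
#' @param fisher_z apply atanh to off-diagonal entries (default FALSE).
#' @return C x C numeric matrix of class `fc_matrix`.
#' @export
pearson_fc <- function(tc, fisher_z = FALSE) {
  X <- if (inherits(tc, "timecourse")) tc$data else as.matrix(tc)
  .stop_if(!is.numeric(X) || nrow(X) < 3L,
           "need a numeric matrix with at least 3 timepoints")
  .stop_if(anyNA(X), "missing values in time courses")
  v <- apply(X, 2L, var)
  degen <- which(v == 0)
  R <- suppressWarnings(cor(X))
  diag(R) <- 1
  if (length(degen)) {
    R[degen, ] <- NA_real_
    R[, degen] <- NA_real_
    warning("constant column(s) produce undefined correlations: ",
            paste(degen, collapse = ", "), call. = FALSE)
  }
  if (fisher_z) {
    off <- row(R) != col(R)
    R[off] <- atanh(pmin(pmax(R[off], -1 + 1e-15), 1 - 1e-15))
  }
  class(R) <- c("fc_matrix", class(R))
  R
}

#' Vectorize a connectivity matrix to edge features
#'
#' Extracts the upper triangle in the canonical flat-edge order of
#' [edge_index()]; a 53 x 53 matrix yields the 1378 connectivity features
#' used throughout the pipeline.
#'
#' @param fc square symmetric matrix (e.g. from [pearson_fc()]).
#' @param idx optional [edge_index()]; defaults to `edge_index(ncol(fc))`.
#' @return named numeric vector of length C(C-1)/2.
#' @export
vectorize_fc <- function(fc, idx = NULL) {
  fc <- unclass(fc)
  .stop_if(!is.matrix(fc) || nrow(fc) != ncol(fc), "fc must be square")
  idx <- idx %||% edge_index(ncol(fc))
  .stop_if(idx$n_components != ncol(fc),
           "edge index dimension does not match the matrix")
  setNames(fc[cbind(idx$i, idx$j)], edge_names(idx))
}

#' Rebuild a symmetric matrix from an edge vector
#'
#' Inverse of [vectorize_fc()] with unit diagonal; convenient for displaying
#' cluster centroids as connectivity matrices.
#'
#' @param v edge vector in flat order.
#' @param idx optional [edge_index()]; inferred from `length(v)` if omitted.
#' @return C x C symmetric matrix with unit diagonal.
#' @export
unvectorize_fc <- function(v, idx = NULL) {
  if (is.null(idx)) {
    C <- (1 + sqrt(1 + 8 * length(v))) / 2
    .stop_if(C != round(C), "length(v) is not C(C-1)/2 for any integer C")
    idx <- edge_index(as.integer(C))
  }
  .stop_if(length(v) != idx$n_edges, "edge vector length does not match index")
  M <- diag(idx$n_components)
  M[cbind(idx$i, idx$j)] <- v
  M[cbind(idx$j, idx$i)] <- v
  M
}

#' Network contribution of an edge set
#'
#' Summarizes which resting-state networks an edge set involves. The default
#' `endpoint` method counts each edge's two endpoints, so percentages sum to
#' 100 across networks (an edge internal to one network contributes both
#' endpoints there; an edge spanning two networks contributes 50/50). The
#' `incident` alternative reports, per network, the percentage of edges
#' touching that network (sums can exceed 100).
#'
#' @param edges integer flat edge indices (nonempty).
#' @param idx an [edge_index()].
#' @param partition a `network_partition` covering the components.
#' @param method `"endpoint"` (default) or `"incident"`.
#' @return named numeric vector of percentages over all partition networks.
#' @export
network_contribution <- function(edges, idx, partition,
                                 method = c("endpoint", "incident")) {
  method <- match.arg(method)
  .stop_if(length(edges) == 0L,
           "empty edge set: contribution percentages are undefined")
  .stop_if(!inherits(idx, "edge_index"), "idx must be an edge_index")
  .stop_if(nrow(partition) < idx$n_components,
           "partition does not cover all components")
  edges <- as.integer(edges)
  .stop_if(any(edges < 1L | edges > idx$n_edges), "edge index out of range")
  nets <- unique(partition$network)
  net_i <- partition$network[idx$i[edges]]
  net_j <- partition$network[idx$j[edges]]
  if (method == "endpoint") {
    tab <- table(factor(c(net_i, net_j), levels = nets))
    pct <- 100 * as.numeric(tab) / (2 * length(edges))
  } else {
    pct <- vapply(nets, function(nw) {
      100 * mean(net_i == nw | net_j == nw)
    }, numeric(1))
  }
  setNames(pct, nets)
}

#' Association-sign labels for edge statistics
#'
#' Labels each edge by the sign of its GLM coefficient: positive
#' associations (stronger connectivity with higher outcome), negative
#' associations, or `"null"` for an exactly zero coefficient.
#'
#' @param stats data.frame with a `beta` column (e.g. `discovery$stats`).
#' @return character vector of labels.
#' @export
edge_sign_labels <- function(stats) {
  beta <- if (is.data.frame(stats)) stats$beta else as.numeric(stats)
  .stop_if(is.null(beta), "stats must contain a beta column")
  out <- ifelse(beta > 0, "positive-association",
                ifelse(beta < 0, "negative-association", "null"))
  out[is.na(beta)] <- NA_character_
  out
}
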