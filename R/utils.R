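# shared internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

.stop_if <- function(cond, ...) {
  if (isTRUE(cond)) stop(..., call. = FALSE)
  invisible(NULL)
}

.is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x >= 1
}

.is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# deterministic child seed; kept below 2^31 - 1
.derive_seed <- function(seed, offset) {
  (as.numeric(seed) * 101 + as.numeric(offset)) %% 2147483629
}

#' Repair a symmetric matrix to the nearest valid correlation matrix
#'
#' Eigenvalue clipping followed by renormalization to unit diagonal. Used by
#' the synthetic generators when a planted perturbation pushes a target
#' correlation matrix out of the positive-definite cone.
#'
#' @param S symmetric matrix with unit diagonal (approximately).
#' @param eps smallest eigenvalue allowed after clipping.
#' @return list with `mat` (repaired matrix) and `repaired` (logical).
#' @keywords internal
repair_correlation <- function(S, eps = 1e-6) {
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) > eps) {
    return(list(mat = S, repaired = FALSE))
  }
  v <- pmax(e$values, eps)
  M <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(M))
  M <- M / tcrossprod(d)
  M <- (M + t(M)) / 2
  diag(M) <- 1
  list(mat = M, repaired = TRUE)
}

# exact small-vector linear convolution (full / "open" mode)
.conv_open <- function(a, b) {
  na <- length(a)
  nb <- length(b)
  out <- numeric(na + nb - 1L)
  for (i in seq_len(na)) {
    span <- i:(i + nb - 1L)
    out[span] <- out[span] + a[i] * b
  }
  out
}

# all permutations of 1..k (k small), in lexicographic order
.permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(k - 1L)
  out <- matrix(0L, nrow(sub) * k, k)
  row <- 0L
  for (first in seq_len(k)) {
    rest <- setdiff(seq_len(k), first)
    for (r in seq_len(nrow(sub))) {
      row <- row + 1L
      out[row, ] <- c(first, rest[sub[r, ]])
    }
  }
  out
}
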