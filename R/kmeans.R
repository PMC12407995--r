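# Seeded Lloyd k-means over pooled windowed-connectivity rows, with a
# deterministic empty-cluster rule and a per-iteration objective trace.

# one Lloyd run from given initial centers; ties in assignment go to the
# lowest-index centroid for determinism
.lloyd <- function(X, centers, max_iter) {
  n <- nrow(X)
  k <- nrow(centers)
  rsX <- rowSums(X^2)
  a <- integer(0)
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    d2 <- rsX - 2 * tcrossprod(X, centers) +
      matrix(rowSums(centers^2), n, k, byrow = TRUE)
    d2[d2 < 0] <- 0
    a_new <- max.col(-d2, ties.method = "first")
    # empty-cluster rule: reseed each empty centroid at the point currently
    # farthest from its assigned centroid (deterministic under the seed)
    repeat {
      sizes <- tabulate(a_new, k)
      empty <- which(sizes == 0L)
      if (!length(empty)) break
      dmin <- d2[cbind(seq_len(n), a_new)]
      for (e in empty) {
        far <- which.max(dmin)
        a_new[far] <- e
        dmin[far] <- -Inf
      }
    }
    trace <- c(trace, sum(d2[cbind(seq_len(n), a_new)]))
    if (length(a) && all(a_new == a)) {
      converged <- TRUE
      break
    }
    a <- a_new
    centers <- rowsum(X, a) / tabulate(a, k)
  }
  list(assignment = a_new, centers = centers,
       inertia = trace[length(trace)], trace = trace, converged = converged)
}

#' K-means clustering of windowed connectivity into states
#'
#' Lloyd's algorithm under the squared-Euclidean objective on the pooled
#' subject-by-window rows of a dynamic connectivity tensor, run from
#' `n_init` seeded random initializations (centers drawn from the data
#' rows); the solution with the lowest within-cluster sum of squares wins.
#' Assignment ties break to the lowest-index centroid, and an emptied
#' cluster is deterministically re-seeded at the point farthest from its
#' current centroid, so results are bitwise reproducible given `seed` and
#' independent of any parallel configuration (the computation is
#' single-threaded).
#'
#' @param dfnc a [dfnc_tensor()] or a plain rows x features matrix.
#' @param k number of states (>= 1; at most the number of rows).
#' @param n_init number of seeded initializations (default 10).
#' @param max_iter maximum Lloyd iterations per initialization (default
#'   1000).
#' @param seed integer seed (mandatory).
#' @return object of class `state_model`: `k`, `centroids` (k x E),
#'   `assignment` (pooled row labels), `state_vectors` (per-subject label
#'   sequences), `occupancy` via [occupancy_table()], `inertia`,
#'   `inertia_trace` (objective after each assignment step of the winning
#'   run), `seed`, `n_init`, `max_iter`, `converged`.
#' @export
cluster_states <- function(dfnc, k, n_init = 10, max_iter = 1000, seed) {
  .stop_if(missing(seed) || !.is_number(seed), "an integer seed is mandatory")
  .stop_if(!.is_count(k), "k must be a positive integer")
  .stop_if(!.is_count(n_init) || !.is_count(max_iter),
           "n_init and max_iter must be positive integers")
  stk <- .stack_dfnc(dfnc)
  X <- stk$X
  .stop_if(anyNA(X), "NA windowed correlations; remove degenerate windows first")
  n <- nrow(X)
  .stop_if(k > n, "k exceeds the number of pooled windows")

  set.seed(as.integer(seed))
  best <- NULL
  for (init in seq_len(n_init)) {
    centers0 <- X[sample.int(n, k), , drop = FALSE]
    fit <- .lloyd(X, centers0, max_iter)
    if (is.null(best) || fit$inertia < best$inertia) best <- fit
  }
  sv <- split(best$assignment, factor(stk$subject, levels = unique(stk$subject)))
  structure(
    list(k = as.integer(k), centroids = best$centers,
         assignment = best$assignment, state_vectors = sv,
         inertia = best$inertia, inertia_trace = best$trace,
         seed = as.integer(seed), n_init = as.integer(n_init),
         max_iter = as.integer(max_iter), converged = best$converged),
    class = "state_model"
  )
}

#' @export
print.state_model <- function(x, ...) {
  cat(sprintf("<state_model> k = %d over %d windows (%d subjects); inertia %.4g%s\n",
              x$k, length(x$assignment), length(x$state_vectors), x$inertia,
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Elbow selection of the number of states
#'
#' Runs [cluster_states()] for each candidate k and computes the dispersion
#' ratio r(k) = within-cluster sum of squares / between-cluster sum of
#' squares. The elbow is formalized as the k with maximum discrete curvature
#' (second difference r(k-1) - 2 r(k) + r(k+1)) over the interior of the
#' candidate range, ties going to the smaller k. If clustering at the
#' smallest candidate already leaves essentially no within-cluster
#' dispersion (r below 1e-8), that k is returned directly -- the
#' point-mass degenerate case has its knee at the first candidate.
#'
#' @param dfnc a [dfnc_tensor()] or matrix.
#' @param k_range candidate cluster counts (default 2:9).
#' @param seed integer seed (mandatory).
#' @param n_init,max_iter passed to [cluster_states()].
#' @return list with `k` (selected), `k_range`, `within`, `between`,
#'   `ratio`, `curvature`.
#' @export
elbow_k <- function(dfnc, k_range = 2:9, seed, n_init = 10, max_iter = 1000) {
  .stop_if(missing(seed) || !.is_number(seed), "an integer seed is mandatory")
  ks <- sort(unique(as.integer(k_range)))
  .stop_if(length(ks) < 1L || any(ks < 1L), "invalid k_range")
  stk <- .stack_dfnc(dfnc)
  X <- stk$X
  .stop_if(anyNA(X), "NA windowed correlations; remove degenerate windows first")
  tot <- sum(sweep(X, 2L, colMeans(X))^2)
  .stop_if(tot <= 0, "degenerate data: all pooled windows are identical")
  .stop_if(max(ks) > nrow(X), "k_range exceeds the number of pooled windows")

  within <- vapply(seq_along(ks), function(m) {
    cluster_states(X, ks[m], n_init = n_init, max_iter = max_iter,
                   seed = .derive_seed(seed, m))$inertia
  }, numeric(1))
  between <- tot - within
  ratio <- within / pmax(between, .Machine$double.eps)

  curvature <- rep(NA_real_, length(ks))
  if (length(ks) >= 3L) {
    mid <- 2:(length(ks) - 1L)
    curvature[mid] <- ratio[mid - 1L] - 2 * ratio[mid] + ratio[mid + 1L]
  }
  if (ratio[1L] <= 1e-8) {
    k_sel <- ks[1L]
  } else if (all(is.na(curvature))) {
    k_sel <- ks[which.min(ratio)]
  } else {
    k_sel <- ks[which.max(curvature)]   # NA-safe: interior only; ties -> smaller k
  }
  list(k = as.integer(k_sel), k_range = ks, within = within,
       between = between, ratio = ratio, curvature = curvature)
}
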