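# Mass-univariate edge-wise GLM machinery.
#
# All fits share one algebraic core: the covariate design X is factored
# once (QR); outcome and edge columns are residualized against X
# (Frisch-Waugh), and the edge-term statistics of the full OLS model
# "outcome ~ X + edge" are recovered from the residual cross-products with
# df = n - rank(X) - 1. This is exactly equivalent to refitting the full
# model per edge, and is what makes 1378-edge scans over thousands of
# subjects cheap.

# y: response vector; E: matrix whose columns are added one at a time;
# edge_as "predictor": stats for column as regressor of y ~ X + e
# edge_as "response":  stats for y as regressor of e ~ X + y (per column)
.edge_glm_engine <- function(y, E, X, edge_as = c("predictor", "response")) {
  edge_as <- match.arg(edge_as)
  E <- as.matrix(E)
  n <- length(y)
  .stop_if(nrow(E) != n || nrow(X) != n, "row mismatch between inputs")
  qrX <- qr(X)
  .stop_if(qrX$rank < ncol(X), "design matrix is rank deficient")
  df <- n - qrX$rank - 1L
  .stop_if(df < 1L, "too few subjects for the design (n <= rank + 1)")

  cm <- colMeans(E)
  ss0 <- colSums(E^2) - n * cm^2
  const <- ss0 <= 1e-12 * pmax(1, colSums(E^2))

  ry <- qr.resid(qrX, y)
  RE <- qr.resid(qrX, E)
  ss_e <- colSums(RE^2)
  ss_y <- sum(ry^2)
  xy <- drop(crossprod(RE, ry))

  if (edge_as == "predictor") {
    beta <- xy / ss_e
    rss <- pmax(ss_y - xy^2 / ss_e, 0)
    se <- sqrt(rss / df / ss_e)
  } else {
    beta <- xy / ss_y
    rss <- pmax(ss_e - xy^2 / ss_y, 0)
    se <- sqrt(rss / df / ss_y)
  }
  t <- beta / se
  t[se == 0 & beta != 0] <- sign(beta[se == 0 & beta != 0]) * Inf
  p <- 2 * pt(abs(t), df, lower.tail = FALSE)
  partial_r <- ifelse(is.finite(t), sign(t) * sqrt(t^2 / (t^2 + df)), sign(t))

  out <- data.frame(beta = beta, se = se, t = t, p = p,
                    partial_r = partial_r, df = df, constant = const)
  out[const, c("beta", "se", "t", "p", "partial_r")] <- NA_real_
  rownames(out) <- colnames(E)
  out
}

#' Edge-term GLM for a single connectivity feature
#'
#' Ordinary least squares of the outcome on the covariate design augmented
#' with one edge column; returns the statistics of the edge term: `beta`
#' (outcome units per unit correlation), `se`, `t`, two-sided `p` from the
#' t distribution with `df = n - rank(design) - 1`, and the effect-size
#' correlate `partial_r = sign(t) * sqrt(t^2 / (t^2 + df))`.
#'
#' A constant edge has no estimable coefficient and is skipped with
#' `skipped = TRUE` and NA statistics; a rank-deficient design is an error.
#'
#' @param edge_values per-subject edge values.
#' @param outcome per-subject outcome values (same order).
#' @param design a `design_matrix` from [build_design()], or a plain numeric
#'   design matrix including the intercept.
#' @return list with `beta`, `se`, `t`, `p`, `partial_r`, `df`, `skipped`.
#' @export
fit_edge_glm <- function(edge_values, outcome, design) {
  X <- if (inherits(design, "design_matrix")) design$matrix else as.matrix(design)
  st <- .edge_glm_engine(as.numeric(outcome),
                         matrix(as.numeric(edge_values), ncol = 1), X,
                         edge_as = "predictor")
  if (st$constant[1L]) {
    warning("constant edge: coefficient not estimable; skipped", call. = FALSE)
  }
  list(beta = st$beta[1L], se = st$se[1L], t = st$t[1L], p = st$p[1L],
       partial_r = st$partial_r[1L], df = st$df[1L], skipped = st$constant[1L])
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment; rejecting all q <= alpha
#' reproduces the classic BH rule over the supplied family. Inputs must be
#' finite probabilities (NA/NaN are an error so that a family is never
#' silently shrunk).
#'
#' @param p_values numeric vector in \[0, 1\].
#' @return vector of adjusted q-values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  .stop_if(length(p_values) == 0L, "empty p-value vector")
  .stop_if(any(!is.finite(p_values)), "NA/NaN p-values are not allowed")
  .stop_if(any(p_values < 0 | p_values > 1), "p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

.as_selected_edges <- function(edges) {
  if (inherits(edges, "discovery_result")) {
    sel <- edges$selected
  } else {
    sel <- as.integer(edges)
  }
  .stop_if(length(sel) == 0L, "empty discovery set")
  .stop_if(anyDuplicated(sel) > 0L, "duplicated edge indices")
  sel
}

.make_discovery <- function(stats, alpha, outcome_name, n, terms, n_dropped,
                            seed = NULL) {
  q_ok <- !is.na(stats$q)
  sel <- which(q_ok & stats$q <= alpha)
  sel <- sel[order(stats$p[sel], sel)]
  structure(
    list(stats = stats, selected = as.integer(sel), alpha = alpha,
         outcome = outcome_name, n = n, terms = terms,
         n_dropped = n_dropped, seed = seed),
    class = "discovery_result"
  )
}

#' @export
print.discovery_result <- function(x, ...) {
  cat(sprintf("<discovery> outcome '%s': %d/%d edges at q <= %g (n = %d)\n",
              x$outcome, length(x$selected), nrow(x$stats), x$alpha, x$n))
  invisible(x)
}

#' Edge-wise GLM discovery with FDR selection
#'
#' Fits the covariate-adjusted GLM `outcome ~ covariates + edge` for every
#' connectivity feature, applies Benjamini-Hochberg FDR across exactly that
#' family (all C(C-1)/2 edges), and returns the edges with q <= alpha
#' ordered by ascending p, together with the full per-edge statistics table.
#'
#' @param edge_table subjects x edges matrix (rownames = subject ids), e.g.
#'   from [read_edge_table()] or [gen_static_cohort()].
#' @param outcome numeric outcome vector named by subject id.
#' @param covariates covariate data.frame with `subject_id`.
#' @param alpha FDR level in (0, 1\]; `alpha = 1` returns every edge.
#' @param terms covariate terms for [build_design()].
#' @return object of class `discovery_result`: `stats` (per-edge data.frame
#'   with edge, i, j, beta, se, t, p, q, partial_r, df), `selected` (flat
#'   edge indices, ascending p), `alpha`, `n`, `terms`, `n_dropped`.
#' @export
discover <- function(edge_table, outcome, covariates, alpha = 0.05,
                     terms = c("age", "age2", "sex", "agexsex", "site")) {
  .stop_if(!.is_number(alpha) || alpha <= 0 || alpha > 1,
           "alpha must be in (0, 1]")
  al <- .align_cases(edge_table, outcome, covariates, terms)
  X <- build_design(al$covariates, terms)$matrix
  st <- .edge_glm_engine(al$y, al$E, X, edge_as = "predictor")
  C <- (1 + sqrt(1 + 8 * ncol(al$E))) / 2
  idx <- edge_index(as.integer(C))
  q <- rep(NA_real_, nrow(st))
  ok <- !st$constant
  if (any(ok)) q[ok] <- bh_fdr(st$p[ok])
  stats <- data.frame(edge = seq_len(idx$n_edges),
                      i = idx$i, j = idx$j,
                      beta = st$beta, se = st$se, t = st$t, p = st$p, q = q,
                      partial_r = st$partial_r, df = st$df)
  .make_discovery(stats, alpha,
                  outcome_name = attr(outcome, "outcome_name") %||% "outcome",
                  n = length(al$y), terms = terms, n_dropped = al$n_dropped)
}

#' Covariate-adjusted two-group edge comparison
#'
#' Same machinery as [discover()] but with a binary group indicator as the
#' regressor of interest: per edge, `edge ~ covariates + group`, so `beta`
#' is the adjusted group difference in correlation units. FDR is applied
#' across all edges as in [discover()]. Used for present/absent phenotypes
#' (e.g. anhedonia versus healthy controls).
#'
#' @param edge_table subjects x edges matrix.
#' @param group 0/1 vector named by subject id; both groups must be nonempty.
#' @param covariates covariate data.frame.
#' @param alpha FDR level.
#' @param terms covariate terms.
#' @return a `discovery_result`.
#' @export
group_discover <- function(edge_table, group, covariates, alpha = 0.05,
                           terms = c("age", "age2", "sex", "agexsex", "site")) {
  .stop_if(!.is_number(alpha) || alpha <= 0 || alpha > 1,
           "alpha must be in (0, 1]")
  al <- .align_cases(edge_table, group, covariates, terms)
  g <- al$y
  .stop_if(!all(g %in% c(0, 1)), "group must be coded 0/1")
  .stop_if(length(unique(g)) < 2L, "both groups must be nonempty")
  X <- build_design(al$covariates, terms)$matrix
  st <- .edge_glm_engine(g, al$E, X, edge_as = "response")
  C <- (1 + sqrt(1 + 8 * ncol(al$E))) / 2
  idx <- edge_index(as.integer(C))
  q <- rep(NA_real_, nrow(st))
  ok <- !st$constant
  if (any(ok)) q[ok] <- bh_fdr(st$p[ok])
  stats <- data.frame(edge = seq_len(idx$n_edges),
                      i = idx$i, j = idx$j,
                      beta = st$beta, se = st$se, t = st$t, p = st$p, q = q,
                      partial_r = st$partial_r, df = st$df)
  .make_discovery(stats, alpha, outcome_name = "group", n = length(g),
                  terms = terms, n_dropped = al$n_dropped)
}

#' Permutation validation of a discovered edge set
#'
#' Re-tests each discovered edge under `n_perm` random shuffles of the
#' outcome vector (covariate and edge rows stay aligned to subjects, so the
#' shuffle also breaks outcome-covariate links, matching the procedure of
#' shuffling the behavioral scores and rerunning the regression). The
#' empirical p-value uses the add-one convention
#' `(1 + #\{|t*| >= |t_obs|\}) / (1 + n_perm)`, so it is never exactly zero
#' and its minimum is `1/(n_perm + 1)`.
#'
#' Fully deterministic given `seed`; computed single-threaded so results do
#' not depend on any worker configuration.
#'
#' @param edge_table subjects x edges matrix.
#' @param outcome named outcome vector.
#' @param covariates covariate data.frame.
#' @param edges a `discovery_result` or integer vector of flat edge indices.
#' @param n_perm number of shuffles (default 1000).
#' @param seed integer seed (mandatory).
#' @param terms covariate terms.
#' @return data.frame with `edge`, `t_obs`, `perm_p`.
#' @export
permutation_validate <- function(edge_table, outcome, covariates, edges,
                                 n_perm = 1000, seed,
                                 terms = c("age", "age2", "sex", "agexsex", "site")) {
  .stop_if(missing(seed) || !.is_number(seed), "an integer seed is mandatory")
  .stop_if(!.is_count(n_perm), "n_perm must be a positive integer")
  sel <- .as_selected_edges(edges)
  al <- .align_cases(edge_table, outcome, covariates, terms)
  X <- build_design(al$covariates, terms)$matrix
  E <- al$E[, sel, drop = FALSE]
  y <- al$y
  n <- length(y)

  qrX <- qr(X)
  df <- n - qr(X)$rank - 1L
  RE <- qr.resid(qrX, E)
  ss_e <- colSums(RE^2)
  .stop_if(any(ss_e <= 1e-12), "constant edge among the selected set")

  obs <- .edge_glm_engine(y, E, X, edge_as = "predictor")
  t_obs2 <- obs$t^2

  set.seed(as.integer(seed))
  m <- length(sel)
  count <- numeric(m)
  block <- 200L
  done <- 0L
  while (done < n_perm) {
    B <- min(block, n_perm - done)
    Yp <- vapply(seq_len(B), function(b) y[sample.int(n)], numeric(n))
    RY <- qr.resid(qrX, Yp)
    XY <- crossprod(RE, RY)                  # m x B
    ssy <- colSums(RY^2)                      # B
    num <- XY^2 / ss_e                        # m x B
    rss <- sweep(-num, 2L, ssy, "+")          # m x B residual SS
    rss[rss < 0] <- 0
    t2 <- df * num / rss
    count <- count + rowSums(t2 >= matrix(t_obs2, m, B))
    done <- done + B
  }
  data.frame(edge = sel, t_obs = obs$t,
             perm_p = (1 + count) / (1 + n_perm))
}

#' Subsample size for bootstrap sensitivity analysis
#'
#' `round(frac * n)`: at the default 70% fraction, a cohort of 14047
#' subjects yields subsamples of 9833.
#'
#' @param n number of subjects.
#' @param frac subsampling fraction in (0, 1\].
#' @return integer subsample size.
#' @export
subsample_size <- function(n, frac = 0.70) {
  .stop_if(!.is_count(n), "n must be a positive integer")
  .stop_if(!.is_number(frac) || frac <= 0 || frac > 1, "frac must be in (0, 1]")
  as.integer(round(frac * n))
}

#' Bootstrap subsampling sensitivity of edge discovery
#'
#' Repeats the full discovery (edge-wise GLM plus BH-FDR selection) on
#' `n_boot` random subsamples of `round(frac * n)` subjects drawn without
#' replacement (set `replace = TRUE` for a classical bootstrap) and returns
#' each edge's selection frequency, a stability measure for the discovered
#' set. Deterministic given `seed`.
#'
#' @param edge_table subjects x edges matrix.
#' @param outcome named outcome vector.
#' @param covariates covariate data.frame.
#' @param alpha FDR level applied within each subsample.
#' @param n_boot number of subsampling iterations (default 1000).
#' @param frac subsample fraction (default 0.70).
#' @param seed integer seed (mandatory).
#' @param replace draw with replacement (default FALSE).
#' @param terms covariate terms.
#' @return data.frame with `edge` and `boot_freq` in \[0, 1\].
#' @export
bootstrap_sensitivity <- function(edge_table, outcome, covariates,
                                  alpha = 0.05, n_boot = 1000, frac = 0.70,
                                  seed, replace = FALSE,
                                  terms = c("age", "age2", "sex", "agexsex", "site")) {
  .stop_if(missing(seed) || !.is_number(seed), "an integer seed is mandatory")
  .stop_if(!.is_count(n_boot), "n_boot must be a positive integer")
  al <- .align_cases(edge_table, outcome, covariates, terms)
  X <- build_design(al$covariates, terms)$matrix
  n <- length(al$y)
  m <- subsample_size(n, frac)
  .stop_if(m <= ncol(X) + 1L,
           "subsample size ", m, " is too small for the design rank")
  set.seed(as.integer(seed))
  counts <- numeric(ncol(al$E))
  for (b in seq_len(n_boot)) {
    rows <- sample.int(n, m, replace = replace)
    st <- .edge_glm_engine(al$y[rows], al$E[rows, , drop = FALSE],
                           X[rows, , drop = FALSE], edge_as = "predictor")
    ok <- !st$constant
    q <- rep(NA_real_, length(ok))
    q[ok] <- bh_fdr(st$p[ok])
    counts <- counts + as.numeric(!is.na(q) & q <= alpha)
  }
  data.frame(edge = seq_len(ncol(al$E)), boot_freq = counts / n_boot)
}
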