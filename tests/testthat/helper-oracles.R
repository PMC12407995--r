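# Independent oracles and small fixture builders used across the suite.
# Each oracle deliberately takes the most naive computational route so it
# shares no code path with the implementation it checks.

# two-pass Pearson correlation: centered dot product over centered norms
naive_pearson <- function(x, y) {
  mx <- mean(x)
  my <- mean(y)
  num <- sum((x - mx) * (y - my))
  num / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

naive_fc_matrix <- function(X) {
  C <- ncol(X)
  R <- diag(C)
  for (a in seq_len(C - 1)) {
    for (b in (a + 1):C) {
      R[a, b] <- R[b, a] <- naive_pearson(X[, a], X[, b])
    }
  }
  R
}

# literal Benjamini-Hochberg step-up: find the largest rank with
# p_(i) <= i*q/m by scanning thresholds, then invert to adjusted values
stepup_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(ps[i:m] * m / (i:m))
  }
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# full-model least-squares oracle for the edge term via lm()
lm_edge_oracle <- function(edge, outcome, X) {
  df <- as.data.frame(X[, -1, drop = FALSE])
  df$edge <- edge
  df$y <- outcome
  fit <- stats::lm(y ~ ., data = df)
  s <- summary(fit)$coefficients["edge", ]
  list(beta = s[["Estimate"]], se = s[["Std. Error"]],
       t = s[["t value"]], p = s[["Pr(>|t|)"]],
       df = fit$df.residual)
}

# naive weighted-moment correlation for one window and one pair
naive_weighted_cor <- function(x, y, w) {
  w <- w / sum(w)
  mx <- sum(w * x)
  my <- sum(w * y)
  cxy <- sum(w * (x - mx) * (y - my))
  cxx <- sum(w * (x - mx)^2)
  cyy <- sum(w * (y - my)^2)
  cxy / sqrt(cxx * cyy)
}

# direct evaluation of the rectangle*Gaussian convolution at each window lag
naive_taper <- function(len, sigma) {
  radius <- ceiling(3 * sigma)
  x <- (-radius):radius
  g <- exp(-x^2 / (2 * sigma^2))
  full_len <- len + 2 * radius
  full <- vapply(seq_len(full_len), function(k) {
    # conv[k] = sum over rectangle positions i with kernel index k - i + 1
    acc <- 0
    for (i in seq_len(len)) {
      ki <- k - i + 1
      if (ki >= 1 && ki <= length(g)) acc <- acc + g[ki]
    }
    acc
  }, numeric(1))
  w <- full[radius + seq_len(len)]
  w / sum(w)
}

# adjusted Rand index between two labelings
rand_index_adj <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- sum(choose(tab, 2))
  a_comb <- sum(choose(rowSums(tab), 2))
  b_comb <- sum(choose(colSums(tab), 2))
  expected <- a_comb * b_comb / choose(n, 2)
  maxi <- (a_comb + b_comb) / 2
  (sum_comb - expected) / (maxi - expected)
}

# small covariate table without the categorical extras, for cheap GLM tests
tiny_covariates <- function(n, seed) {
  set.seed(seed)
  data.frame(subject_id = sprintf("S%05d", seq_len(n)),
             age = runif(n, 30, 70),
             sex = rbinom(n, 1, 0.5),
             site = sample(c("a", "b"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# subjects x edges matrix of plain noise "edge" features in [-1, 1]
tiny_edge_table <- function(n, n_edges_components, seed, sd = 0.2) {
  set.seed(seed)
  idx <- edge_index(n_edges_components)
  E <- matrix(tanh(rnorm(n * idx$n_edges, 0, sd)), n, idx$n_edges,
              dimnames = list(sprintf("S%05d", seq_len(n)), edge_names(idx)))
  E
}
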