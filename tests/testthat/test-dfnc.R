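# Tapered windows, windowed correlations, state clustering and occupancy.

test_that("taper weights are symmetric, positive, normalized, and match a direct convolution", {
  for (cfg in list(c(20, 3), c(20, 1), c(15, 2.5), c(8, 0.8))) {
    tp <- make_taper(cfg[1], cfg[2])
    w <- tp$weights
    expect_length(w, cfg[1])
    expect_true(all(w > 0))
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_equal(w, rev(w), tolerance = 1e-12)
    expect_equal(w, naive_taper(cfg[1], cfg[2]), tolerance = 1e-12)
  }
  # sigma -> 0 limit recovers the uniform rectangle
  expect_equal(make_taper(20, 1e-6)$weights, rep(1 / 20, 20),
               tolerance = 1e-9)
  tp <- make_taper(20, 3)
  expect_gt(max(tp$weights), tp$weights[1])
  ratio <- tp$weights[1] / max(tp$weights)
  expect_true(ratio > 0 && ratio < 1)
  expect_error(make_taper(20, 0), "sigma")
})

test_that("sliding windows count floor((T - length)/step) + 1", {
  expect_length(sliding_windows(229, 20, 1), 210)
  expect_identical(sliding_windows(20, 20), 1L)
  expect_identical(sliding_windows(25, 20, 5), c(1L, 6L))
  expect_error(sliding_windows(19, 20), "shorter")
})

test_that("weighted correlations reduce to Pearson under uniform weights and match the moment oracle", {
  set.seed(55)
  X <- matrix(rnorm(30 * 4), 30, 4)
  idx <- edge_index(4)
  flat <- make_taper(20, 1e-9)   # numerically uniform
  wfc <- weighted_fc(X, 6, flat)
  static <- vectorize_fc(pearson_fc(X[6:25, ]), idx)
  expect_equal(wfc, static, tolerance = 1e-9)

  tp <- make_taper(20, 3)
  got <- weighted_fc(X, 3, tp)
  for (k in seq_len(idx$n_edges)) {
    a <- X[3:22, idx$i[k]]
    b <- X[3:22, idx$j[k]]
    expect_equal(unname(got[k]), naive_weighted_cor(a, b, tp$weights),
                 tolerance = 1e-12)
  }
  # identical columns correlate at 1 regardless of weights
  Y <- cbind(X[, 1], X[, 1], X[, 2])
  expect_equal(unname(weighted_fc(Y, 1, tp, edges = 1L)), 1, tolerance = 1e-12)
})

test_that("the dfnc tensor equals per-window weighted correlations", {
  set.seed(65)
  tcs <- lapply(1:3, function(i) matrix(rnorm(60 * 5), 60, 5))
  edges <- c(1L, 4L, 7L, 10L)
  tens <- dfnc_tensor(tcs, edges, window = 20, sigma = 3, step = 4)
  tp <- make_taper(20, 3)
  for (s in 1:3) {
    for (wi in seq_along(tens$starts)) {
      expect_equal(tens$data[[s]][wi, ],
                   weighted_fc(tcs[[s]], tens$starts[wi], tp, edges = edges),
                   tolerance = 1e-10)
    }
  }
  expect_equal(nrow(tens$data[[1]]), length(sliding_windows(60, 20, 4)))
})

test_that("state clustering recovers well-separated patterns exactly", {
  set.seed(75)
  centers <- rbind(c(5, 0, 0, 0), c(0, 5, 0, 0), c(0, 0, 5, 0))
  lab <- sample(1:3, 600, replace = TRUE)
  X <- centers[lab, ] + matrix(rnorm(600 * 4, 0, 0.2), 600, 4)
  m <- cluster_states(X, k = 3, seed = 7)
  expect_equal(rand_index_adj(m$assignment, lab), 1.0)
  # objective is monotone over Lloyd iterations
  expect_true(all(diff(m$inertia_trace) <= 1e-8))
  # same seed twice -> identical assignments
  m2 <- cluster_states(X, k = 3, seed = 7)
  expect_identical(m$assignment, m2$assignment)
  expect_identical(m$centroids, m2$centroids)
  # independent library implementation reaches the same optimum here
  km <- stats::kmeans(X, centers = 3, nstart = 10, iter.max = 100)
  expect_equal(m$inertia, km$tot.withinss, tolerance = 1e-6)
})

test_that("k = 1 returns the global mean and total sum of squares", {
  set.seed(85)
  X <- matrix(rnorm(50 * 3), 50, 3)
  m <- cluster_states(X, k = 1, seed = 1)
  expect_equal(as.numeric(m$centroids), colMeans(X), tolerance = 1e-12)
  expect_equal(m$inertia, sum(sweep(X, 2, colMeans(X))^2), tolerance = 1e-8)
  expect_error(cluster_states(X[1:2, ], k = 5, seed = 1), "exceeds")
})

test_that("elbow selection finds the knee and handles degenerate masses", {
  # two perfectly separated point masses -> k = 2
  X2 <- rbind(matrix(1, 40, 3), matrix(-1, 40, 3))
  el2 <- elbow_k(X2, k_range = 2:5, seed = 3)
  expect_identical(el2$k, 2L)
  expect_length(el2$ratio, 4L)

  set.seed(95)
  centers <- rbind(c(4, 0, 0), c(0, 4, 0), c(0, 0, 4))
  lab <- sample(1:3, 900, replace = TRUE)
  X3 <- centers[lab, ] + matrix(rnorm(900 * 3, 0, 0.4), 900, 3)
  el3 <- elbow_k(X3, k_range = 2:6, seed = 4)
  expect_identical(el3$k, 3L)
  # within-cluster dispersion shrinks with k (up to sampling noise)
  expect_true(all(diff(el3$within) <= 1e-6))

  expect_error(elbow_k(matrix(1, 30, 3), k_range = 2:4, seed = 1),
               "degenerate")
})

test_that("occupancy rates count windows and conserve mass", {
  expect_equal(unname(occupancy(c(1, 1, 2, 3), 3)), c(0.5, 0.25, 0.25))
  expect_equal(unname(occupancy(rep(2, 7), 3)), c(0, 1, 0))
  sv <- rep(c(1, 2, 3), times = c(105, 63, 42))
  expect_equal(unname(occupancy(sv, 3)), c(0.5, 0.3, 0.2))
  expect_error(occupancy(integer(0), 3), "empty")
  expect_error(occupancy(c(1, 4), 3), "1\\.\\.k")
})

test_that("occupancy-symptom GLMs respect compositional antisymmetry at k = 2", {
  set.seed(105)
  n <- 80
  ocr1 <- runif(n, 0.2, 0.8)
  ocr <- cbind(OCR_1 = ocr1, OCR_2 = 1 - ocr1)
  rownames(ocr) <- sprintf("S%05d", 1:n)
  cv <- tiny_covariates(n, seed = 205)
  y <- setNames(5 * ocr1 + rnorm(n, 0, 0.5), rownames(ocr))
  g <- ocr_glm(ocr, y, cv, terms = c("age", "sex"))
  expect_equal(g$beta[1], -g$beta[2], tolerance = 1e-10)
  expect_equal(abs(g$t[1]), abs(g$t[2]), tolerance = 1e-10)
})

test_that("occupancy-symptom GLMs recover a planted coupling with correct signs", {
  set.seed(115)
  n <- 306
  raw <- matrix(rexp(n * 3), n, 3)
  ocr <- raw / rowSums(raw)
  colnames(ocr) <- paste0("OCR_", 1:3)
  rownames(ocr) <- sprintf("S%05d", 1:n)
  cv <- tiny_covariates(n, seed = 215)
  y <- setNames(10 * ocr[, 2] + rnorm(n, 0, 1), rownames(ocr))
  g <- ocr_glm(ocr, y, cv, terms = c("age", "sex", "site"))
  expect_gt(g$beta[2], 0)
  expect_lte(g$q[2], 0.05)
  # compositional complements point the other way
  expect_lt(g$beta[1], 0)
  expect_lt(g$beta[3], 0)
})

test_that("state matching resolves label permutations", {
  ref <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  est <- ref[c(3, 1, 2), ] + 0.01
  map <- match_states(est, ref)
  expect_identical(map, c(2L, 3L, 1L))
})
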