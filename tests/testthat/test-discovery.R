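# Edge-wise GLM, FDR selection, permutation and bootstrap machinery.

test_that("fit_edge_glm agrees with a full lm() refit on random problems", {
  set.seed(31)
  for (rep in 1:30) {
    n <- 40
    cv <- tiny_covariates(n, seed = 100 + rep)
    X <- build_design(cv, c("age", "sex", "site"))$matrix
    edge <- rnorm(n)
    y <- 0.4 * edge + X %*% rnorm(ncol(X)) + rnorm(n)
    got <- fit_edge_glm(edge, y, X)
    want <- lm_edge_oracle(edge, as.numeric(y), X)
    expect_equal(got$beta, want$beta, tolerance = 1e-8)
    expect_equal(got$se, want$se, tolerance = 1e-8)
    expect_equal(got$t, want$t, tolerance = 1e-8)
    expect_equal(got$p, want$p, tolerance = 1e-8)
    expect_equal(got$df, want$df)
    expect_equal(got$partial_r,
                 sign(got$t) * sqrt(got$t^2 / (got$t^2 + got$df)),
                 tolerance = 1e-12)
  }
})

test_that("a noiseless linear relation drives p to its limit", {
  edge <- c(-1, 0, 1, 2, 3)
  got <- fit_edge_glm(edge, 2 * edge, matrix(1, 5, 1))
  expect_equal(got$beta, 2)
  expect_equal(got$se, 0)
  expect_equal(got$p, 0)
  expect_warning(fit_edge_glm(rep(0.5, 5), rnorm(5), matrix(1, 5, 1)),
                 "constant edge")
})

test_that("null edges give uniform p-values", {
  set.seed(41)
  n <- 500
  cv <- tiny_covariates(n, seed = 41)
  X <- build_design(cv, c("age", "sex"))$matrix
  y <- rnorm(n)
  p <- vapply(1:200, function(e) fit_edge_glm(rnorm(n), y, X)$p, numeric(1))
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("bh_fdr implements the step-up rule", {
  # thresholds i*alpha/m = 0.0125, 0.025, 0.0375, 0.05: all four rejected
  q <- bh_fdr(c(0.01, 0.02, 0.03, 0.04))
  expect_true(all(q <= 0.05))
  expect_identical(bh_fdr(rep(1, 6)), rep(1, 6))
  expect_equal(bh_fdr(0.04), 0.04)  # m = 1 identity
  expect_error(bh_fdr(c(0.1, NaN)), "NA/NaN")
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
  # exact agreement with the brute-force step-up oracle
  set.seed(51)
  for (rep in 1:300) {
    p <- runif(sample(1:50, 1))^sample(1:3, 1)
    expect_equal(bh_fdr(p), stepup_bh(p), tolerance = 1e-15)
  }
})

test_that("discover selects planted edges and alpha = 1 returns everything", {
  planted <- c(3L, 10L, 20L)
  sens <- fdp <- numeric(5)
  for (s in 1:5) {
    sp <- static_cohort_spec(n_subjects = 400, n_components = 10,
                             n_timepoints = 120,
                             planted_edges = data.frame(edge = planted,
                                                        effect = 0.3),
                             seed = s)
    co <- gen_static_cohort(sp)
    d <- discover(co$edges, co$outcome, co$covariates)
    sens[s] <- length(intersect(d$selected, planted)) / length(planted)
    fdp[s] <- if (length(d$selected))
      length(setdiff(d$selected, planted)) / length(d$selected) else 0
    # selection is ordered by ascending p
    expect_identical(order(d$stats$p[d$selected]), seq_along(d$selected))
    expect_true(all(d$stats$q >= d$stats$p, na.rm = TRUE))
  }
  expect_gte(mean(sens), 0.9)
  expect_lte(mean(fdp), 0.15)

  sp0 <- static_cohort_spec(n_subjects = 200, n_components = 8,
                            n_timepoints = 100, seed = 77)
  co0 <- gen_static_cohort(sp0)
  d_all <- discover(co0$edges, co0$outcome, co0$covariates, alpha = 1)
  expect_length(d_all$selected, edge_index(8)$n_edges)
})

test_that("discover stays near-silent under a global null", {
  total <- 0
  for (s in 1:5) {
    sp <- static_cohort_spec(n_subjects = 500, n_components = 10,
                             n_timepoints = 120, seed = 200 + s)
    co <- gen_static_cohort(sp)
    total <- total + length(discover(co$edges, co$outcome, co$covariates)$selected)
  }
  expect_lte(total, 2)
})

test_that("permutation p attains its floor under perfect association and is seeded", {
  n <- 60
  cv <- tiny_covariates(n, seed = 61)
  E <- tiny_edge_table(n, 5, seed = 61)
  y <- setNames(3 * E[, 4], rownames(E))   # perfect association, edge 4
  pv <- permutation_validate(E, y, cv, edges = 4L, n_perm = 99, seed = 5,
                             terms = c("age", "sex"))
  expect_equal(pv$perm_p, 1 / 100)
  pv2 <- permutation_validate(E, y, cv, edges = 4L, n_perm = 99, seed = 5,
                              terms = c("age", "sex"))
  expect_identical(pv, pv2)
})

test_that("permutation p is calibrated for pure-noise edges", {
  n <- 120
  hits <- 0L
  reps <- 200L
  for (r in seq_len(reps)) {
    set.seed(3000 + r)
    E <- matrix(rnorm(n), n, 1,
                dimnames = list(sprintf("S%05d", 1:n), "e_1_2"))
    y <- setNames(rnorm(n), rownames(E))
    cv <- tiny_covariates(n, seed = 3000 + r)
    pv <- permutation_validate(E, y, cv, edges = 1L, n_perm = 200,
                               seed = 9000 + r, terms = c("age", "sex"))
    hits <- hits + (pv$perm_p <= 0.05)
  }
  expect_lt(abs(hits / reps - 0.05), 0.04)
})

test_that("bootstrap subsampling sizes, stability and determinism", {
  expect_equal(subsample_size(14047, 0.70), 9833L)
  expect_equal(subsample_size(10, 0.70), 7L)

  planted <- data.frame(edge = 5L, effect = 0.35)
  sp <- static_cohort_spec(n_subjects = 400, n_components = 8,
                           n_timepoints = 120, planted_edges = planted,
                           seed = 91)
  co <- gen_static_cohort(sp)
  bs <- bootstrap_sensitivity(co$edges, co$outcome, co$covariates,
                              n_boot = 100, seed = 13)
  expect_gte(bs$boot_freq[5], 0.95)
  bs2 <- bootstrap_sensitivity(co$edges, co$outcome, co$covariates,
                               n_boot = 100, seed = 13)
  expect_identical(bs, bs2)
  expect_error(
    bootstrap_sensitivity(co$edges[1:12, ], co$outcome, co$covariates,
                          n_boot = 5, seed = 1),
    "too small")
})

test_that("group comparison recovers a mean-shifted edge and rejects degenerate groups", {
  n <- 400
  set.seed(71)
  E <- tiny_edge_table(n, 8, seed = 71)
  cv <- tiny_covariates(n, seed = 71)
  g <- setNames(rbinom(n, 1, 0.5), rownames(E))
  E[, 6] <- tanh(atanh(E[, 6]) + 0.35 * g)   # adjusted group shift on edge 6
  d <- group_discover(E, g, cv, terms = c("age", "sex", "site"))
  expect_true(6L %in% d$selected)
  expect_lte(length(setdiff(d$selected, 6L)), 2L)

  g0 <- setNames(rep(1, n), rownames(E))
  expect_error(group_discover(E, g0, cv, terms = c("age", "sex")),
               "nonempty")
})
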