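# Generator determinism, ground-truth bookkeeping and marginal calibration.

test_that("identical spec and seed reproduce static cohorts exactly", {
  sp <- static_cohort_spec(n_subjects = 30, n_components = 6,
                           n_timepoints = 50,
                           planted_edges = data.frame(edge = 2L, effect = 0.3),
                           seed = 8)
  a <- gen_static_cohort(sp)
  b <- gen_static_cohort(sp)
  expect_identical(a$edges, b$edges)
  expect_identical(a$outcome, b$outcome)
  expect_identical(a$covariates, b$covariates)
  sp2 <- static_cohort_spec(n_subjects = 30, n_components = 6,
                            n_timepoints = 50,
                            planted_edges = data.frame(edge = 2L, effect = 0.3),
                            seed = 9)
  expect_false(identical(gen_static_cohort(sp2)$edges, a$edges))
})

test_that("identical spec and seed reproduce dynamic cohorts exactly", {
  sp <- dynamic_cohort_spec(n_subjects = 8, n_components = 6,
                            n_timepoints = 80, seed = 4)
  a <- gen_dynamic_cohort(sp)
  b <- gen_dynamic_cohort(sp)
  expect_identical(a$truth$states, b$truth$states)
  expect_identical(a$symptom, b$symptom)
  expect_identical(a$timecourses[[3]]$data, b$timecourses[[3]]$data)
})

test_that("generator truth OCRs equal occupancy of the true window labels", {
  sp <- dynamic_cohort_spec(n_subjects = 12, n_components = 6,
                            n_timepoints = 100, seed = 14)
  dc <- gen_dynamic_cohort(sp)
  for (i in 1:12) {
    expect_identical(unname(dc$truth$ocr[i, ]),
                     unname(occupancy(dc$truth$window_labels[i, ], 3)))
  }
  expect_equal(max(abs(rowSums(dc$truth$ocr) - 1)), 0)
  # transition matrix is stochastic with the configured dwell
  expect_equal(rowSums(dc$truth$transition), rep(1, 3))
  expect_equal(diag(dc$truth$transition), rep(1 - 1 / 30, 3))
})

test_that("edge marginals match the base structure within Monte-Carlo error", {
  sp <- static_cohort_spec(n_subjects = 200, n_components = 8,
                           n_timepoints = 120, edge_age_effect = 0,
                           edge_sex_effect = 0, seed = 19)
  co <- gen_static_cohort(sp)
  idx <- edge_index(8)
  part <- sp$partition
  within <- part$network[idx$i] == part$network[idx$j]
  # per-edge means over 200 subjects; sampling se ~ (1/sqrt(119))/sqrt(200)
  means <- colMeans(co$edges)
  if (any(within)) {
    expect_lt(max(abs(means[within] - 0.25)), 0.03)
  }
  expect_lt(max(abs(means[!within] - 0)), 0.03)
})

test_that("extreme planted perturbations trigger logged positive-definite repair", {
  S <- matrix(0.99, 3, 3)
  S[1, 2] <- S[2, 1] <- -0.99
  diag(S) <- 1
  rep <- edgeproject:::repair_correlation(S)
  expect_true(rep$repaired)
  expect_equal(diag(rep$mat), rep(1, 3))
  expect_gte(min(eigen(rep$mat, symmetric = TRUE)$values), 0)

  # a spec engineered to leave the positive-definite cone still yields
  # valid correlations, with repairs counted
  many <- data.frame(edge = edge_of(rep(1L, 5), 2:6, edge_index(6)),
                     effect = 0.95)
  sp <- static_cohort_spec(n_subjects = 25, n_components = 6,
                           n_timepoints = 40, base_within = 0.6,
                           planted_edges = many, seed = 33)
  co <- gen_static_cohort(sp)
  expect_true(all(abs(co$edges) <= 1))
  expect_gte(co$truth$repairs, 0)
})

test_that("paired cohorts validate shared edges and transfer structure", {
  ref <- static_cohort_spec(n_subjects = 60, n_components = 6,
                            n_timepoints = 50,
                            planted_edges = data.frame(edge = c(2L, 5L),
                                                       effect = 0.3),
                            seed = 41)
  tgt <- static_cohort_spec(n_subjects = 40, n_components = 6,
                            n_timepoints = 50, cohort = "target",
                            planted_edges = data.frame(edge = 2L,
                                                       effect = 0.25),
                            seed = 42)
  pair <- gen_two_cohorts(ref, tgt)
  expect_identical(pair$shared_edges, 2L)
  expect_true("trauma_type" %in% names(pair$target$covariates))
  expect_false("trauma_type" %in% names(pair$reference$covariates))
  expect_error(gen_two_cohorts(ref, tgt, shared_edges = 5L), "planted in both")
})

test_that("single-state dynamic cohorts are flagged degenerate downstream", {
  sp <- dynamic_cohort_spec(n_subjects = 6, n_components = 6,
                            n_timepoints = 60, k_true = 1, coupling = 0,
                            seed = 51)
  dc <- gen_dynamic_cohort(sp)
  expect_true(all(dc$truth$states == 1L))
  expect_identical(dc$truth$min_separation, Inf)
  tens <- dfnc_tensor(dc$timecourses, edges = 1:10)
  # clustering a single regime at k = 2 splits noise near-evenly and the
  # elbow curve shows no pronounced knee
  m <- cluster_states(tens, k = 2, seed = 5)
  ocr <- occupancy_table(m)
  expect_lt(abs(mean(ocr[, 1]) - 0.5), 0.35)
  el <- elbow_k(tens, k_range = 2:5, seed = 6)
  expect_lt(max(abs(diff(el$ratio))) / el$ratio[1], 0.5)
})
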