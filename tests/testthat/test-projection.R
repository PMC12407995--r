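# Constrained out-of-sample testing of a discovered edge set.

test_that("a single-edge family has q equal to p", {
  sp <- static_cohort_spec(n_subjects = 150, n_components = 6,
                           n_timepoints = 80, cohort = "target", seed = 3)
  co <- gen_static_cohort(sp)
  pr <- project_edges(co$edges, 7L, co$outcome, co$covariates)
  expect_equal(pr$stats$q, pr$stats$p)
  expect_equal(pr$m, 1L)
})

test_that("projecting a cohort onto its own discovery set is self-consistent", {
  sp <- static_cohort_spec(n_subjects = 400, n_components = 10,
                           n_timepoints = 120,
                           planted_edges = data.frame(edge = c(4L, 17L),
                                                      effect = 0.35),
                           seed = 12)
  co <- gen_static_cohort(sp)
  terms <- c("age", "age2", "sex", "agexsex", "site")
  d <- discover(co$edges, co$outcome, co$covariates, terms = terms)
  expect_gte(length(d$selected), 1L)
  pr <- project_edges(co$edges, d, co$outcome, co$covariates,
                      terms = terms)
  expect_true(all(pr$stats$q <= d$alpha))
})

test_that("restricting the family preserves or increases rejections", {
  sp <- static_cohort_spec(n_subjects = 306, n_components = 10,
                           n_timepoints = 120, cohort = "target",
                           planted_edges = data.frame(edge = c(3L, 21L, 40L),
                                                      effect = c(0.25, 0.2, 0.15)),
                           seed = 23)
  co <- gen_static_cohort(sp)
  terms <- c("age", "sex", "site")
  whole <- discover(co$edges, co$outcome, co$covariates, terms = terms)
  family <- c(3L, 21L, 40L, 1L, 2L, 5L, 9L)
  pr <- project_edges(co$edges, family, co$outcome, co$covariates,
                      terms = terms)
  whole_hits <- intersect(whole$selected, family)
  restricted_hits <- pr$stats$edge[pr$stats$q <= pr$alpha]
  expect_true(all(whole_hits %in% restricted_hits))
})

test_that("null target symptoms produce (almost) no projected discoveries", {
  hits <- 0L
  for (s in 1:5) {
    sp <- static_cohort_spec(n_subjects = 306, n_components = 10,
                             n_timepoints = 100, cohort = "target",
                             seed = 400 + s)
    co <- gen_static_cohort(sp)
    pr <- project_edges(co$edges, 1:28, co$outcome, co$covariates)
    hits <- hits + sum(pr$stats$q <= 0.05)
  }
  expect_lte(hits, 2L)
})

test_that("projection validates its inputs", {
  sp <- static_cohort_spec(n_subjects = 100, n_components = 6,
                           n_timepoints = 60, cohort = "target", seed = 5)
  co <- gen_static_cohort(sp)
  expect_error(project_edges(co$edges, integer(0), co$outcome, co$covariates),
               "empty discovery set")
  cv <- co$covariates
  cv$income <- NULL
  expect_error(project_edges(co$edges, 1L, co$outcome, cv), "income")
})

test_that("projection report carries the standard tuple, ordered by p", {
  part <- make_partition(10)
  sp <- static_cohort_spec(n_subjects = 306, n_components = 10,
                           n_timepoints = 120, cohort = "target",
                           planted_edges = data.frame(edge = c(3L, 10L),
                                                      effect = c(0.3, -0.3)),
                           seed = 31)
  co <- gen_static_cohort(sp)
  pr <- project_edges(co$edges, c(3L, 10L, 20L, 25L), co$outcome,
                      co$covariates)
  rep <- projection_report(pr, part)
  expect_identical(names(rep)[1:4],
                   c("symptom", "edge", "component_i", "component_j"))
  if (nrow(rep) >= 2) {
    expect_true(all(diff(rep$p) >= 0))
    lab <- rep$direction[rep$edge == 3]
    expect_identical(lab, "positive-association")
  }
  # empty significant set keeps the header intact
  pr0 <- pr
  pr0$stats$q <- 1
  rep0 <- projection_report(pr0, part, alpha = 0.05)
  expect_equal(nrow(rep0), 0L)
  expect_true("beta" %in% names(rep0))
})
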