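# End-to-end orchestration: outputs, caching, determinism, config errors.

wf_config <- function(seed = 42) {
  run_config(
    seed = seed, n_perm = 60, n_boot = 30, k = "auto", k_range = 2:4,
    simulate = list(
      reference = list(n_subjects = 250, n_components = 10,
                       n_timepoints = 100,
                       planted_edges = data.frame(edge = c(3L, 10L),
                                                  effect = 0.35)),
      target = list(n_subjects = 150, n_components = 10, n_timepoints = 100,
                    planted_edges = data.frame(edge = 3L, effect = 0.3)),
      dynamic = list(n_subjects = 30, n_components = 6, n_timepoints = 100)),
    dfnc_edges = 1:15)
}

test_that("the pipeline produces every stage artifact and a truthful report", {
  out <- file.path(tempdir(), "wf-run-a")
  res <- suppressMessages(run_pipeline(wf_config(), out))
  files <- list.files(out)
  for (f in c("config_resolved.json", "edge_stats_reaction_time.csv",
              "discovery_reaction_time.json", "perm_reaction_time.csv",
              "boot_reaction_time.csv", "projection_reaction_time_pcl5.csv",
              "ocr.csv", "ocr_glm.csv", "state_model.json",
              "state_vectors.csv", "report.md", "log.txt")) {
    expect_true(f %in% files, label = paste("missing", f))
  }
  report <- readLines(file.path(out, "report.md"))
  expect_true(any(grepl("Truth versus found", report)))
  expect_true(any(grepl("Top 5 edges", report)))
  expect_gte(length(res$discovery$selected), 1L)
  ocr <- utils::read.csv(file.path(out, "ocr.csv"))
  expect_equal(rowSums(ocr[, -1]), rep(1, nrow(ocr)), tolerance = 1e-12)
})

test_that("rerunning the same config and seed is numerically identical", {
  out1 <- file.path(tempdir(), "wf-run-b1")
  out2 <- file.path(tempdir(), "wf-run-b2")
  suppressMessages(run_pipeline(wf_config(), out1))
  suppressMessages(run_pipeline(wf_config(), out2))
  for (f in c("edge_stats_reaction_time.csv", "perm_reaction_time.csv",
              "boot_reaction_time.csv", "projection_reaction_time_pcl5.csv",
              "ocr.csv", "ocr_glm.csv", "state_vectors.csv", "report.md")) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)), label = f)
  }
})

test_that("cached discovery reuse leaves downstream numbers unchanged", {
  out <- file.path(tempdir(), "wf-run-c")
  suppressMessages(run_pipeline(wf_config(), out))
  proj1 <- readLines(file.path(out, "projection_reaction_time_pcl5.csv"))
  log1 <- readLines(file.path(out, "log.txt"))
  expect_false(any(grepl("reusing cached", log1)))
  suppressMessages(run_pipeline(wf_config(), out, overwrite = FALSE))
  log2 <- readLines(file.path(out, "log.txt"))
  expect_true(any(grepl("reusing cached", log2)))
  expect_identical(readLines(file.path(out, "projection_reaction_time_pcl5.csv")),
                   proj1)
})

test_that("configs without a seed are rejected", {
  expect_error(run_config(), "seed is mandatory")
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(list(alpha = 0.05), f, auto_unbox = TRUE)
  expect_error(read_run_config(f), "seed is mandatory")
})

test_that("discovery sets serialize to JSON and back", {
  sp <- static_cohort_spec(n_subjects = 150, n_components = 6,
                           n_timepoints = 60,
                           planted_edges = data.frame(edge = 4L, effect = 0.4),
                           seed = 77)
  co <- gen_static_cohort(sp)
  d <- discover(co$edges, co$outcome, co$covariates)
  f <- tempfile(fileext = ".json")
  write_discovery(d, f)
  d2 <- read_discovery(f)
  expect_identical(d2$selected, d$selected)
  expect_equal(d2$alpha, d$alpha)
  expect_identical(d2$terms, d$terms)
})
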