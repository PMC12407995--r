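# Orchestration: one config in, a run directory of tables, serialized
# results and a markdown report out.

#' Assemble a run configuration
#'
#' Collects every tunable of the discover-validate-project-dynamics
#' sequence with the pipeline defaults (FDR level 0.05; 1000 permutations;
#' 1000 bootstrap iterations at 70% subsampling; window 20 TRs with Gaussian
#' sigma 3 and step 1; candidate states 2..9). A seed is mandatory -- every
#' run must be reproducible -- and each run writes a frozen copy of the
#' resolved configuration.
#'
#' Data enter either through `simulate` (nested argument lists for
#' [static_cohort_spec()] under `reference`/`target` and
#' [dynamic_cohort_spec()] under `dynamic`) or through `data` (paths:
#' `reference_edges`, `reference_pheno`, `outcome`, `target_edges`,
#' `target_pheno`, `symptoms`, `timecourse_dir`).
#'
#' @param seed integer seed (mandatory).
#' @param alpha FDR level.
#' @param n_perm permutation count (0 disables the stage).
#' @param n_boot bootstrap iteration count (0 disables the stage).
#' @param boot_frac bootstrap subsampling fraction.
#' @param window,sigma,step dynamic-connectivity window settings.
#' @param k number of states, or `"auto"` for elbow selection.
#' @param k_range candidate k values for the elbow.
#' @param n_init k-means initializations.
#' @param reference_terms,target_terms covariate terms per cohort.
#' @param simulate,data input blocks (exactly one must be supplied to
#'   [run_pipeline()]).
#' @param dfnc_edges optional explicit edge subset for the dynamic stage;
#'   defaults to the union of discovered edges.
#' @return list of class `run_config`.
#' @export
run_config <- function(seed, alpha = 0.05, n_perm = 1000, n_boot = 1000,
                       boot_frac = 0.70, window = 20, sigma = 3, step = 1,
                       k = "auto", k_range = 2:9, n_init = 10,
                       reference_terms = c("age", "age2", "sex", "agexsex", "site"),
                       target_terms = c("age", "sex", "age2", "agexsex",
                                        "income", "education_years", "site",
                                        "trauma_type"),
                       simulate = NULL, data = NULL, dfnc_edges = NULL) {
  .stop_if(missing(seed) || is.null(seed) || !.is_number(seed),
           "config error: an integer seed is mandatory")
  structure(
    list(seed = as.integer(seed), alpha = alpha, n_perm = n_perm,
         n_boot = n_boot, boot_frac = boot_frac, window = window,
         sigma = sigma, step = step, k = k,
         k_range = as.integer(k_range), n_init = n_init,
         reference_terms = reference_terms, target_terms = target_terms,
         simulate = simulate, data = data, dfnc_edges = dfnc_edges),
    class = "run_config"
  )
}

#' Read a run configuration from JSON
#'
#' @param path JSON file whose keys match the arguments of [run_config()].
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  .stop_if(!file.exists(path), "config file not found: ", path)
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  .stop_if(is.null(raw$seed), "config error: an integer seed is mandatory")
  args <- raw[intersect(names(raw), names(formals(run_config)))]
  do.call(run_config, args)
}

#' Serialize a discovery set to JSON
#'
#' Stores the selected edges with their provenance (outcome, alpha, cohort
#' size, covariate terms, per-edge p) so a projection can be run without
#' re-fitting the reference cohort.
#'
#' @param discovery a `discovery_result`.
#' @param path output JSON path.
#' @export
write_discovery <- function(discovery, path) {
  .stop_if(!inherits(discovery, "discovery_result"),
           "discovery must be a discovery_result")
  jsonlite::write_json(
    list(outcome = discovery$outcome, alpha = discovery$alpha,
         n = discovery$n, terms = discovery$terms,
         n_edges = if (is.null(discovery$stats)) NA else nrow(discovery$stats),
         selected = discovery$selected,
         p = if (is.null(discovery$stats)) NULL
             else discovery$stats$p[discovery$selected]),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read a serialized discovery set
#'
#' @param path JSON written by [write_discovery()].
#' @return a minimal `discovery_result` (selection + provenance).
#' @export
read_discovery <- function(path) {
  .stop_if(!file.exists(path), "discovery file not found: ", path)
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  structure(
    list(stats = NULL, selected = as.integer(raw$selected),
         alpha = raw$alpha, outcome = raw$outcome, n = raw$n,
         terms = raw$terms, n_dropped = NA_integer_, seed = NULL),
    class = "discovery_result"
  )
}

.wf_log <- function(logfile, ...) {
  line <- paste0(...)
  cat(line, "\n", file = logfile, append = TRUE, sep = "")
  message(line)
}

.wf_stage <- function(name, logfile, expr) {
  .wf_log(logfile, "[stage] ", name)
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

.md_table <- function(df, digits = 4) {
  if (nrow(df) == 0L) return("(none)")
  fmt <- vapply(df, function(col) {
    if (is.numeric(col)) formatC(col, digits = digits, format = "g") else
      as.character(col)
  }, character(nrow(df)))
  fmt <- matrix(fmt, nrow = nrow(df))
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(fmt, 1L, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  paste(c(header, sep, rows), collapse = "\n")
}

#' Run the full discover-validate-project-dynamics pipeline
#'
#' Executes the stages in order -- data loading or simulation, edge-wise
#' discovery with FDR, permutation validation, bootstrap sensitivity,
#' constrained projection, dynamic-state analysis with occupancy-symptom
#' GLMs -- and writes all tables, serialized results, a log and a markdown
#' report into `out_dir`. Any stage error aborts with the stage name;
#' outputs of completed stages are retained. With `overwrite = FALSE` an
#' existing serialized discovery is reused (transparent caching: cached and
#' fresh runs produce identical downstream numbers).
#'
#' @param config a `run_config` (or path to a JSON config).
#' @param out_dir run directory (created if needed).
#' @param overwrite recompute stages whose outputs already exist.
#' @return invisible list with the in-memory results of every stage and the
#'   report path.
#' @export
run_pipeline <- function(config, out_dir, overwrite = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  .stop_if(!inherits(config, "run_config"), "config must be a run_config")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(out_dir, "log.txt")
  cat("", file = logfile)
  cfg_json <- config[!vapply(config, is.null, TRUE)]
  jsonlite::write_json(cfg_json, file.path(out_dir, "config_resolved.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)

  # ---- data -----------------------------------------------------------
  dat <- .wf_stage("data", logfile, {
    if (!is.null(config$simulate)) {
      sim <- config$simulate
      .stop_if(is.null(sim$reference) || is.null(sim$target),
               "simulate block needs reference and target spec lists")
      ref_args <- sim$reference
      ref_args$seed <- ref_args$seed %||% .derive_seed(config$seed, 1)
      tgt_args <- sim$target
      tgt_args$cohort <- tgt_args$cohort %||% "target"
      tgt_args$seed <- tgt_args$seed %||% .derive_seed(config$seed, 2)
      if (!is.null(ref_args$planted_edges))
        ref_args$planted_edges <- as.data.frame(ref_args$planted_edges)
      if (!is.null(tgt_args$planted_edges))
        tgt_args$planted_edges <- as.data.frame(tgt_args$planted_edges)
      pair <- gen_two_cohorts(do.call(static_cohort_spec, ref_args),
                              do.call(static_cohort_spec, tgt_args))
      dyn <- NULL
      if (!is.null(sim$dynamic)) {
        dyn_args <- sim$dynamic
        dyn_args$seed <- dyn_args$seed %||% .derive_seed(config$seed, 3)
        dyn_args$window <- dyn_args$window %||% config$window
        dyn_args$sigma <- dyn_args$sigma %||% config$sigma
        dyn_args$step <- dyn_args$step %||% config$step
        dyn <- gen_dynamic_cohort(do.call(dynamic_cohort_spec, dyn_args))
      }
      list(ref_edges = pair$reference$edges,
           ref_pheno = pair$reference$covariates,
           ref_outcome = pair$reference$outcome,
           tgt_edges = pair$target$edges,
           tgt_pheno = pair$target$covariates,
           tgt_symptoms = setNames(list(pair$target$outcome),
                                   attr(pair$target$outcome, "outcome_name")),
           dynamic = dyn, pair = pair)
    } else {
      d <- config$data
      .stop_if(is.null(d), "config error: either simulate or data is required")
      ref_pheno <- read_covariates(d$reference_pheno)
      tgt_pheno <- if (!is.null(d$target_pheno)) read_covariates(d$target_pheno)
      syms <- NULL
      if (!is.null(tgt_pheno) && !is.null(d$symptoms)) {
        syms <- lapply(d$symptoms, function(s) outcome_vector(tgt_pheno, s))
        names(syms) <- d$symptoms
      }
      dyn <- NULL
      if (!is.null(d$timecourse_dir)) {
        files <- sort(list.files(d$timecourse_dir, full.names = TRUE))
        dyn <- list(timecourses = lapply(files, read_timecourse),
                    covariates = tgt_pheno, symptom = NULL)
      }
      list(ref_edges = read_edge_table(d$reference_edges),
           ref_pheno = ref_pheno,
           ref_outcome = outcome_vector(ref_pheno, d$outcome),
           tgt_edges = if (!is.null(d$target_edges)) read_edge_table(d$target_edges),
           tgt_pheno = tgt_pheno, tgt_symptoms = syms,
           dynamic = dyn, pair = NULL)
    }
  })

  # ---- discovery ------------------------------------------------------
  outcome_name <- attr(dat$ref_outcome, "outcome_name") %||% "outcome"
  disc_json <- file.path(out_dir, sprintf("discovery_%s.json", outcome_name))
  disc <- .wf_stage("discovery", logfile, {
    if (!overwrite && file.exists(disc_json)) {
      .wf_log(logfile, "  reusing cached ", basename(disc_json))
      read_discovery(disc_json)
    } else {
      d <- discover(dat$ref_edges, dat$ref_outcome, dat$ref_pheno,
                    alpha = config$alpha, terms = config$reference_terms)
      utils::write.csv(d$stats,
                       file.path(out_dir, sprintf("edge_stats_%s.csv", outcome_name)),
                       row.names = FALSE)
      write_discovery(d, disc_json)
      d
    }
  })
  .wf_log(logfile, sprintf("  %d edge(s) selected at q <= %g",
                           length(disc$selected), config$alpha))

  # ---- permutation & bootstrap ---------------------------------------
  perm <- boot <- NULL
  if (config$n_perm > 0 && length(disc$selected) > 0) {
    perm <- .wf_stage("permutation", logfile, {
      pv <- permutation_validate(dat$ref_edges, dat$ref_outcome, dat$ref_pheno,
                                 disc, n_perm = config$n_perm,
                                 seed = .derive_seed(config$seed, 11),
                                 terms = config$reference_terms)
      utils::write.csv(pv, file.path(out_dir, sprintf("perm_%s.csv", outcome_name)),
                       row.names = FALSE)
      pv
    })
  }
  if (config$n_boot > 0) {
    boot <- .wf_stage("bootstrap", logfile, {
      bs <- bootstrap_sensitivity(dat$ref_edges, dat$ref_outcome, dat$ref_pheno,
                                  alpha = config$alpha, n_boot = config$n_boot,
                                  frac = config$boot_frac,
                                  seed = .derive_seed(config$seed, 12),
                                  terms = config$reference_terms)
      utils::write.csv(bs, file.path(out_dir, sprintf("boot_%s.csv", outcome_name)),
                       row.names = FALSE)
      bs
    })
  }

  # ---- projection -----------------------------------------------------
  projections <- NULL
  if (!is.null(dat$tgt_edges) && length(dat$tgt_symptoms) > 0 &&
      length(disc$selected) > 0) {
    projections <- .wf_stage("projection", logfile, {
      lapply(names(dat$tgt_symptoms), function(sc) {
        pr <- project_edges(dat$tgt_edges, disc, dat$tgt_symptoms[[sc]],
                            dat$tgt_pheno, alpha = config$alpha,
                            terms = config$target_terms, symptom_name = sc)
        utils::write.csv(pr$stats,
                         file.path(out_dir,
                                   sprintf("projection_%s_%s.csv", outcome_name, sc)),
                         row.names = FALSE)
        pr
      })
    })
  }

  # ---- dynamics -------------------------------------------------------
  dynres <- NULL
  if (!is.null(dat$dynamic)) {
    dynres <- .wf_stage("dfnc", logfile, {
      C_dyn <- ncol(if (inherits(dat$dynamic, "dynamic_cohort"))
        dat$dynamic$timecourses[[1L]]$data else dat$dynamic$timecourses[[1L]]$data)
      idx_dyn <- edge_index(C_dyn)
      subset <- config$dfnc_edges %||% disc$selected
      subset <- subset[subset <= idx_dyn$n_edges]
      .stop_if(length(subset) == 0L,
               "no valid edge subset for the dynamic stage")
      tens <- dfnc_tensor(dat$dynamic$timecourses, subset,
                          window = config$window, sigma = config$sigma,
                          step = config$step)
      k_used <- config$k
      elbow <- NULL
      if (identical(k_used, "auto")) {
        elbow <- elbow_k(tens, k_range = config$k_range,
                         seed = .derive_seed(config$seed, 21),
                         n_init = config$n_init)
        k_used <- elbow$k
      }
      model <- cluster_states(tens, k = k_used, n_init = config$n_init,
                              seed = .derive_seed(config$seed, 22))
      ocr <- occupancy_table(model)
      utils::write.csv(data.frame(subject_id = rownames(ocr), ocr,
                                  check.names = FALSE),
                       file.path(out_dir, "ocr.csv"), row.names = FALSE)
      sv <- do.call(rbind, lapply(names(model$state_vectors), function(id) {
        data.frame(subject_id = id,
                   window = seq_along(model$state_vectors[[id]]),
                   state = model$state_vectors[[id]])
      }))
      utils::write.csv(sv, file.path(out_dir, "state_vectors.csv"),
                       row.names = FALSE)
      jsonlite::write_json(
        list(k = model$k, inertia = model$inertia, seed = model$seed,
             n_init = model$n_init, edges = subset,
             centroids = model$centroids,
             elbow = if (!is.null(elbow))
               list(k_range = elbow$k_range, ratio = elbow$ratio)),
        file.path(out_dir, "state_model.json"),
        auto_unbox = TRUE, digits = NA)
      glm_tab <- NULL
      if (!is.null(dat$dynamic$symptom)) {
        glm_tab <- ocr_glm(ocr, dat$dynamic$symptom, dat$dynamic$covariates,
                           terms = config$target_terms)
        utils::write.csv(glm_tab, file.path(out_dir, "ocr_glm.csv"),
                         row.names = FALSE)
      }
      list(tensor_meta = tens[setdiff(names(tens), "data")], model = model,
           ocr = ocr, elbow = elbow, ocr_glm = glm_tab)
    })
  }

  # ---- report ---------------------------------------------------------
  report <- .wf_stage("report", logfile, {
    C_ref <- (1 + sqrt(1 + 8 * ncol(dat$ref_edges))) / 2
    idx <- edge_index(as.integer(C_ref))
    part <- if (C_ref == 53) default_partition() else make_partition(as.integer(C_ref))
    lines <- c(sprintf("# Pipeline report: %s", outcome_name), "",
               sprintf("- reference subjects: %d", nrow(dat$ref_edges)),
               sprintf("- edges tested: %d", idx$n_edges),
               sprintf("- selected at q <= %g: %d", config$alpha,
                       length(disc$selected)), "")
    if (length(disc$selected) > 0) {
      nc <- network_contribution(disc$selected, idx, part)
      lines <- c(lines, "## Network contribution of the discovered set", "",
                 .md_table(data.frame(network = names(nc),
                                      percent = as.numeric(nc))), "")
      if (!is.null(disc$stats)) {
        ord <- order(disc$stats$p, disc$stats$edge)
        top <- disc$stats[head(ord, 5L),
                          c("edge", "i", "j", "beta", "se", "p", "q")]
        lines <- c(lines, "## Top 5 edges by p", "", .md_table(top), "")
      }
    }
    if (!is.null(perm)) {
      lines <- c(lines, sprintf(
        "Permutation validation: %d/%d selected edges with empirical p <= 0.05 (%d shuffles).",
        sum(perm$perm_p <= 0.05), nrow(perm), config$n_perm), "")
    }
    if (!is.null(boot)) {
      sel_freq <- boot$boot_freq[disc$selected]
      if (length(sel_freq)) {
        lines <- c(lines, sprintf(
          "Bootstrap sensitivity (%d iterations, %.0f%% subsamples): median selection frequency of discovered edges %.2f.",
          config$n_boot, 100 * config$boot_frac, stats::median(sel_freq)), "")
      }
    }
    if (!is.null(projections)) {
      rep_tab <- projection_report(projections, part)
      lines <- c(lines, "## Projection onto target symptoms", "",
                 .md_table(rep_tab), "")
    }
    if (!is.null(dynres)) {
      lines <- c(lines, "## Dynamic states", "",
                 sprintf("- k = %d (inertia %.4g)", dynres$model$k,
                         dynres$model$inertia),
                 sprintf("- mean occupancy: %s",
                         paste(sprintf("%.3f", colMeans(dynres$ocr)),
                               collapse = ", ")), "")
      if (!is.null(dynres$ocr_glm)) {
        lines <- c(lines, "### Occupancy-symptom associations", "",
                   .md_table(dynres$ocr_glm), "")
      }
    }
    if (!is.null(dat$pair) && !is.null(disc$stats)) {
      planted <- dat$pair$reference$truth$planted$edge
      if (length(planted)) {
        hit <- intersect(planted, disc$selected)
        fdp <- if (length(disc$selected))
          length(setdiff(disc$selected, planted)) / length(disc$selected) else 0
        lines <- c(lines, "## Truth versus found (synthetic run)", "",
                   sprintf("- planted edges: %d; recovered: %d (sensitivity %.2f)",
                           length(planted), length(hit),
                           length(hit) / length(planted)),
                   sprintf("- observed false-discovery proportion: %.3f", fdp), "")
      }
    }
    path <- file.path(out_dir, "report.md")
    writeLines(lines, path)
    path
  })
  .wf_log(logfile, "[done] report at ", report)
  invisible(list(config = config, data = dat, discovery = disc,
                 permutation = perm, bootstrap = boot,
                 projections = projections, dynamics = dynres,
                 report = report))
}
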