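# Seeded synthetic cohorts with known ground truth. The static generator
# emulates cross-subject edge strength linearly coupled to a behavior score
# plus covariate effects; the dynamic generator emulates within-scan
# covariance regime-switching among k latent states driven by a Markov
# chain, with symptoms coupled to true state occupancy.

#' Specification of a synthetic static cohort
#'
#' Defines the study conditions for [gen_static_cohort()]. The reference
#' cohort draws ages uniformly on 45-85 with three collection sites and a
#' reaction-time-like outcome; the target cohort draws ages on 18-75 with
#' five sites plus income, years of education and trauma type, and a
#' symptom-scale outcome. Planted effects are standardized: each planted
#' edge's latent correlation moves with the covariate-independent component
#' of the behavior score, calibrated through the correlation-sampling-noise
#' model so that `effect` is the target partial correlation between the
#' observed edge feature and the behavior.
#'
#' @param n_subjects cohort size.
#' @param n_components number of components (default 53).
#' @param n_timepoints scan length in TRs (default 229).
#' @param cohort `"reference"` or `"target"` (sets covariate and outcome
#'   defaults).
#' @param planted_edges data.frame with columns `edge` (flat index) and
#'   `effect` (standardized effect size, |effect| < 1), or NULL for a
#'   global-null cohort.
#' @param base_within,base_between baseline within/between-network latent
#'   correlations of the block-structured base matrix.
#' @param edge_age_effect,edge_sex_effect linear covariate effects on the
#'   latent correlation of the affected edge subset (per centered year of
#'   age; per sex contrast).
#' @param edge_effect_frac fraction of edges carrying the covariate effects
#'   (a deterministic evenly spaced subset).
#' @param outcome_name,outcome_mean,outcome_sd outcome scale: name, mean and
#'   residual (behavior noise) standard deviation.
#' @param outcome_age_effect,outcome_sex_effect covariate effects on the
#'   outcome (per centered year; per sex contrast).
#' @param partition optional `network_partition`; defaults to the packaged
#'   53-component partition or [make_partition()] otherwise.
#' @param tr_seconds repetition time metadata.
#' @param seed integer seed (mandatory; the truth record plus this spec
#'   regenerate the cohort exactly).
#' @return object of class `static_cohort_spec`.
#' @export
static_cohort_spec <- function(n_subjects,
                               n_components = 53,
                               n_timepoints = 229,
                               cohort = c("reference", "target"),
                               planted_edges = NULL,
                               base_within = 0.25,
                               base_between = 0,
                               edge_age_effect = -0.0015,
                               edge_sex_effect = 0.02,
                               edge_effect_frac = 0.1,
                               outcome_name = NULL,
                               outcome_mean = NULL,
                               outcome_sd = NULL,
                               outcome_age_effect = NULL,
                               outcome_sex_effect = NULL,
                               partition = NULL,
                               tr_seconds = 2.36,
                               seed) {
  cohort <- match.arg(cohort)
  .stop_if(missing(seed) || !.is_number(seed), "an integer seed is mandatory")
  .stop_if(!.is_count(n_subjects) || n_subjects < 2, "n_subjects must be >= 2")
  .stop_if(!.is_count(n_components) || n_components < 2,
           "n_components must be >= 2")
  .stop_if(!.is_count(n_timepoints) || n_timepoints < 3,
           "n_timepoints must be >= 3")
  idx <- edge_index(n_components)
  if (!is.null(planted_edges)) {
    .stop_if(!is.data.frame(planted_edges) ||
               !all(c("edge", "effect") %in% names(planted_edges)),
             "planted_edges needs columns edge and effect")
    .stop_if(anyDuplicated(planted_edges$edge) > 0L,
             "planted edges must be distinct")
    .stop_if(any(planted_edges$edge != round(planted_edges$edge)) ||
               any(planted_edges$edge < 1 | planted_edges$edge > idx$n_edges),
             "planted edge indices must be integers in 1..", idx$n_edges)
    planted_edges$edge <- as.integer(planted_edges$edge)
    .stop_if(any(!is.finite(planted_edges$effect)) ||
               any(abs(planted_edges$effect) >= 1),
             "planted effects must be finite with |effect| < 1")
  }
  ref <- cohort == "reference"
  part <- partition %||%
    (if (n_components == 53) default_partition() else make_partition(n_components))
  structure(
    list(n_subjects = as.integer(n_subjects),
         n_components = as.integer(n_components),
         n_timepoints = as.integer(n_timepoints),
         cohort = cohort,
         planted_edges = planted_edges,
         base_within = base_within, base_between = base_between,
         edge_age_effect = edge_age_effect,
         edge_sex_effect = edge_sex_effect,
         edge_effect_frac = edge_effect_frac,
         age_range = if (ref) c(45, 85) else c(18, 75),
         sites = if (ref) c("siteA", "siteB", "siteC")
                 else c("ED1", "ED2", "ED3", "ED4", "ED5"),
         site_probs = if (ref) c(0.40, 0.35, 0.25)
                      else c(0.30, 0.25, 0.20, 0.15, 0.10),
         outcome_name = outcome_name %||% (if (ref) "reaction_time" else "pcl5"),
         outcome_mean = outcome_mean %||% (if (ref) 550 else 30),
         outcome_sd = outcome_sd %||% (if (ref) 80 else 15),
         outcome_age_effect = outcome_age_effect %||% (if (ref) 1.5 else -0.1),
         outcome_sex_effect = outcome_sex_effect %||% (if (ref) 10 else 3),
         partition = part,
         tr_seconds = tr_seconds,
         seed = as.integer(seed)),
    class = "static_cohort_spec"
  )
}

# baseline latent edge correlations from the block network structure
.base_rho <- function(spec, idx) {
  nets <- spec$partition$network
  same <- nets[idx$i] == nets[idx$j]
  ifelse(same, spec$base_within, spec$base_between)
}

# evenly spaced deterministic subset of edges carrying covariate effects
.affected_edges <- function(spec, idx) {
  if (spec$edge_effect_frac <= 0 ||
      (spec$edge_age_effect == 0 && spec$edge_sex_effect == 0)) {
    return(integer(0))
  }
  by <- max(1L, as.integer(round(1 / spec$edge_effect_frac)))
  seq.int(1L, idx$n_edges, by = by)
}

#' Generate a synthetic static cohort with planted edge-behavior couplings
#'
#' Per subject: the latent correlation matrix is the block-structured base
#' plus covariate effects on an affected edge subset plus the planted
#' behavior-dependent perturbation; a T x C Gaussian time series is sampled
#' from it and the empirical correlations form the subject's edge row, so
#' discovery runs on realistically noisy sampled correlations. A target
#' matrix pushed outside the positive-definite cone is repaired by
#' eigenvalue clipping (counted in the truth record); byte-identical output
#' is guaranteed for identical spec + seed.
#'
#' @param spec a [static_cohort_spec()].
#' @return object of class `static_cohort`: list with `edges` (subjects x
#'   edges matrix), `covariates` (data.frame), `outcome` (named vector with
#'   an `outcome_name` attribute) and `truth` (planted table with calibrated
#'   latent slopes, standardized behavior component `z`, affected covariate
#'   edges, baseline correlations, repair count, and the spec itself).
#' @export
gen_static_cohort <- function(spec) {
  .stop_if(!inherits(spec, "static_cohort_spec"),
           "spec must come from static_cohort_spec()")
  set.seed(spec$seed)
  n <- spec$n_subjects
  C <- spec$n_components
  Tn <- spec$n_timepoints
  idx <- edge_index(C)
  ids <- sprintf("S%05d", seq_len(n))
  ref <- spec$cohort == "reference"

  age <- runif(n, spec$age_range[1], spec$age_range[2])
  sex <- rbinom(n, 1, 0.5)
  site <- sample(spec$sites, n, replace = TRUE, prob = spec$site_probs)
  covariates <- data.frame(subject_id = ids, age = age, sex = sex,
                           site = site, stringsAsFactors = FALSE)
  if (!ref) {
    covariates$income <- sample(1:8, n, replace = TRUE)
    covariates$education_years <- sample(8:20, n, replace = TRUE)
    covariates$trauma_type <- sample(
      c("assault", "fall", "mvc", "other", "sexual"), n, replace = TRUE,
      prob = c(0.15, 0.10, 0.50, 0.15, 0.10))
  }

  agemid <- mean(spec$age_range)
  eps <- rnorm(n, 0, spec$outcome_sd)
  y <- spec$outcome_mean +
    spec$outcome_age_effect * (age - agemid) +
    spec$outcome_sex_effect * sex + eps
  z <- eps / spec$outcome_sd   # covariate-independent behavior component

  rho0 <- .base_rho(spec, idx)
  delta <- numeric(idx$n_edges)
  if (!is.null(spec$planted_edges)) {
    pe <- spec$planted_edges
    sig_n <- (1 - rho0[pe$edge]^2) / sqrt(Tn - 1)   # sampling sd of r-hat
    delta[pe$edge] <- pe$effect * sig_n / sqrt(1 - pe$effect^2)
  }
  aff <- .affected_edges(spec, idx)

  perturbed <- any(delta != 0) || length(aff) > 0L
  edges_mat <- matrix(NA_real_, n, idx$n_edges,
                      dimnames = list(ids, edge_names(idx)))
  repairs <- 0L
  if (!perturbed) {
    R0 <- unvectorize_fc(rho0, idx)
    L <- chol(R0)
    for (s in seq_len(n)) {
      X <- matrix(rnorm(Tn * C), Tn, C) %*% L
      edges_mat[s, ] <- vectorize_fc(cor(X), idx)
    }
  } else {
    planted <- which(delta != 0)
    for (s in seq_len(n)) {
      rho <- rho0
      if (length(aff)) {
        rho[aff] <- rho[aff] +
          spec$edge_age_effect * (age[s] - agemid) +
          spec$edge_sex_effect * (sex[s] - 0.5)
      }
      if (length(planted)) {
        rho[planted] <- rho[planted] + delta[planted] * z[s]
      }
      rho <- pmin(pmax(rho, -0.98), 0.98)
      Sg <- unvectorize_fc(rho, idx)
      L <- tryCatch(chol(Sg), error = function(e) NULL)
      if (is.null(L)) {
        repairs <- repairs + 1L
        L <- chol(repair_correlation(Sg)$mat)
      }
      X <- matrix(rnorm(Tn * C), Tn, C) %*% L
      edges_mat[s, ] <- vectorize_fc(cor(X), idx)
    }
  }

  outcome <- setNames(y, ids)
  attr(outcome, "outcome_name") <- spec$outcome_name
  truth <- list(
    planted = if (is.null(spec$planted_edges)) {
      data.frame(edge = integer(), effect = numeric(), delta = numeric())
    } else {
      cbind(spec$planted_edges, delta = delta[spec$planted_edges$edge])
    },
    z = setNames(z, ids),
    affected_edges = aff,
    rho0 = rho0,
    repairs = repairs,
    spec = spec
  )
  structure(list(edges = edges_mat, covariates = covariates,
                 outcome = outcome, truth = truth),
            class = "static_cohort")
}

#' Specification of a synthetic dynamic (regime-switching) cohort
#'
#' Defines the study conditions for [gen_dynamic_cohort()]: `k_true`
#' latent connectivity states, each a block correlation pattern elevating a
#' state-specific component group from `base_r` to `within_r`; a first-order
#' Markov state sequence at TR resolution with self-transition probability
#' `1 - 1/dwell` (so dwell times are geometric with the stated mean); and a
#' symptom linearly coupled to the true window-level occupancy rates,
#' `symptom = intercept + sum_i coupling[i] * OCR_i + noise`.
#'
#' @param n_subjects cohort size (default 306).
#' @param n_components number of components (default 10; kept moderate since
#'   dynamics are computed on a designated edge subset).
#' @param n_timepoints scan length in TRs (default 229; 210 windows at the
#'   default window settings).
#' @param k_true number of latent states (default 3).
#' @param within_r elevated within-group correlation of each state pattern.
#' @param base_r baseline correlation shared by all states.
#' @param dwell mean state dwell time in TRs (default 30).
#' @param coupling length-`k_true` vector of symptom-occupancy slopes
#'   (default `c(0, 10, -10)`: a neutral state, a risk state and an
#'   opposing protective state).
#' @param symptom_intercept,symptom_noise_sd symptom scale location and
#'   noise sd.
#' @param symptom_name outcome label (default "pcl5").
#' @param window,sigma,step window settings used to define window-level
#'   truth (majority state per window).
#' @param tr_seconds repetition time metadata.
#' @param seed integer seed (mandatory).
#' @return object of class `dynamic_cohort_spec`.
#' @export
dynamic_cohort_spec <- function(n_subjects = 306,
                                n_components = 10,
                                n_timepoints = 229,
                                k_true = 3,
                                within_r = 0.7,
                                base_r = 0.1,
                                dwell = 30,
                                coupling = c(0, 10, -10),
                                symptom_intercept = 33,
                                symptom_noise_sd = 1,
                                symptom_name = "pcl5",
                                window = 20, sigma = 3, step = 1,
                                tr_seconds = 2.36,
                                seed) {
  .stop_if(missing(seed) || !.is_number(seed), "an integer seed is mandatory")
  .stop_if(!.is_count(n_subjects), "n_subjects must be a positive integer")
  .stop_if(!.is_count(k_true), "k_true must be a positive integer")
  .stop_if(length(coupling) != k_true,
           "coupling must have one slope per true state")
  .stop_if(!.is_number(dwell) || dwell <= 1, "dwell must exceed 1 TR")
  .stop_if(!.is_count(n_components) || n_components < 2,
           "n_components must be >= 2")
  .stop_if(n_components < k_true,
           "need at least one component per state group")
  .stop_if(!.is_number(within_r) || !.is_number(base_r) ||
             within_r <= base_r || within_r >= 1 || base_r < 0,
           "require 0 <= base_r < within_r < 1")
  structure(
    list(n_subjects = as.integer(n_subjects),
         n_components = as.integer(n_components),
         n_timepoints = as.integer(n_timepoints),
         k_true = as.integer(k_true),
         within_r = within_r, base_r = base_r, dwell = dwell,
         coupling = coupling,
         symptom_intercept = symptom_intercept,
         symptom_noise_sd = symptom_noise_sd,
         symptom_name = symptom_name,
         window = as.integer(window), sigma = sigma, step = as.integer(step),
         tr_seconds = tr_seconds,
         seed = as.integer(seed)),
    class = "dynamic_cohort_spec"
  )
}

# per-state correlation matrices: contiguous component groups, one per state
.state_sigmas <- function(spec) {
  C <- spec$n_components
  k <- spec$k_true
  groups <- if (k == 1L) list(seq_len(C))
            else split(seq_len(C), cut(seq_len(C), k, labels = FALSE))
  lapply(seq_len(k), function(s) {
    S <- matrix(spec$base_r, C, C)
    g <- groups[[s]]
    S[g, g] <- spec$within_r
    diag(S) <- 1
    S
  })
}

#' Generate a synthetic regime-switching dynamic cohort
#'
#' Per subject: a Markov state sequence is simulated at TR resolution, each
#' timepoint is drawn from the active state's covariance, window-level true
#' labels are the majority state within each sliding window (ties go to the
#' state occurring earliest in the window), true occupancy rates are
#' computed from those labels, and the symptom is drawn from the stated
#' linear occupancy coupling. Target-cohort covariates (age, sex, site,
#' income, education, trauma type) are generated alongside so
#' occupancy-symptom GLMs run unchanged.
#'
#' @param spec a [dynamic_cohort_spec()].
#' @return object of class `dynamic_cohort`: `timecourses` (list of
#'   `timecourse`), `symptom` (named vector), `covariates`, and `truth`
#'   (state sequences, window labels, true occupancy matrix, state pattern
#'   vectors over all edges, transition matrix, minimum pattern separation,
#'   coupling, spec).
#' @export
gen_dynamic_cohort <- function(spec) {
  .stop_if(!inherits(spec, "dynamic_cohort_spec"),
           "spec must come from dynamic_cohort_spec()")
  set.seed(spec$seed)
  n <- spec$n_subjects
  C <- spec$n_components
  Tn <- spec$n_timepoints
  k <- spec$k_true
  idx <- edge_index(C)
  ids <- sprintf("A%05d", seq_len(n))

  covariates <- data.frame(
    subject_id = ids,
    age = runif(n, 18, 75),
    sex = rbinom(n, 1, 0.5),
    site = sample(c("ED1", "ED2", "ED3", "ED4", "ED5"), n, replace = TRUE,
                  prob = c(0.30, 0.25, 0.20, 0.15, 0.10)),
    income = sample(1:8, n, replace = TRUE),
    education_years = sample(8:20, n, replace = TRUE),
    trauma_type = sample(c("assault", "fall", "mvc", "other", "sexual"), n,
                         replace = TRUE, prob = c(0.15, 0.10, 0.50, 0.15, 0.10)),
    stringsAsFactors = FALSE
  )

  # transition matrix: geometric dwell with the stated mean
  if (k == 1L) {
    P <- matrix(1, 1, 1)
  } else {
    stay <- 1 - 1 / spec$dwell
    P <- matrix((1 - stay) / (k - 1), k, k)
    diag(P) <- stay
  }
  .stop_if(any(abs(rowSums(P) - 1) > 1e-12), "transition matrix is not stochastic")
  Pcum <- t(apply(P, 1L, cumsum))

  states <- matrix(1L, n, Tn)
  states[, 1L] <- sample.int(k, n, replace = TRUE)
  if (k > 1L) {
    for (t in 2:Tn) {
      u <- runif(n)
      cp <- Pcum[states[, t - 1L], , drop = FALSE]
      states[, t] <- 1L + as.integer(rowSums(u > cp))
    }
  }

  Sigmas <- .state_sigmas(spec)
  Ls <- lapply(Sigmas, function(S) {
    L <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(L)) chol(repair_correlation(S)$mat) else L
  })
  Xflat <- matrix(0, n * Tn, C)   # row (t-1)*n + subject
  sv <- as.vector(states)
  for (s in seq_len(k)) {
    pos <- which(sv == s)
    if (length(pos)) {
      Xflat[pos, ] <- matrix(rnorm(length(pos) * C), ncol = C) %*% Ls[[s]]
    }
  }
  timecourses <- lapply(seq_len(n), function(i) {
    structure(list(subject_id = ids[i],
                   data = Xflat[seq.int(i, by = n, length.out = Tn), ,
                                drop = FALSE],
                   tr_seconds = spec$tr_seconds, degenerate = integer(0)),
              class = "timecourse")
  })

  starts <- sliding_windows(Tn, spec$window, spec$step)
  W <- length(starts)
  counts <- array(0L, c(n, W, k))
  for (s in seq_len(k)) {
    CS <- cbind(0L, t(apply(states == s, 1L, cumsum)))
    counts[, , s] <- CS[, starts + spec$window] - CS[, starts]
  }
  labels <- matrix(1L, n, W)
  if (k > 1L) {
    for (wi in seq_len(W)) {
      cnt <- matrix(counts[, wi, ], n, k)
      mx <- do.call(pmax, as.data.frame(cnt))
      top <- cnt == mx
      lab <- max.col(top, ties.method = "first")
      tied <- rowSums(top) > 1L
      for (r in which(tied)) {   # tie -> state occurring earliest in window
        seg <- states[r, starts[wi]:(starts[wi] + spec$window - 1L)]
        cand <- which(top[r, ])
        lab[r] <- seg[seg %in% cand][1L]
      }
      labels[, wi] <- lab
    }
  }
  true_ocr <- if (k == 1L) {
    matrix(1, n, 1, dimnames = list(NULL, "OCR_1"))
  } else {
    t(apply(labels, 1L, occupancy, k = k))
  }
  rownames(true_ocr) <- ids

  noise <- rnorm(n, 0, spec$symptom_noise_sd)
  symptom <- setNames(
    spec$symptom_intercept + drop(true_ocr %*% spec$coupling) + noise, ids)
  attr(symptom, "outcome_name") <- spec$symptom_name

  patterns <- t(vapply(Sigmas, vectorize_fc, numeric(idx$n_edges), idx = idx))
  min_sep <- if (k > 1L) {
    min(stats::dist(patterns))
  } else {
    Inf
  }
  truth <- list(states = states, window_labels = labels, ocr = true_ocr,
                patterns = patterns, transition = P,
                min_separation = min_sep, coupling = spec$coupling,
                symptom_noise = noise, spec = spec)
  structure(list(timecourses = timecourses, symptom = symptom,
                 covariates = covariates, truth = truth),
            class = "dynamic_cohort")
}

#' Generate a paired reference/target cohort for the full pipeline
#'
#' Emulates the discover-then-project design: a large reference cohort for
#' discovery and a smaller target cohort with the extra covariates
#' (income, education, trauma type) for projection. `shared_edges` names
#' edges planted in both cohorts (effects set independently in each spec);
#' the truth records which discovered edges should truly transfer.
#'
#' @param ref_spec reference [static_cohort_spec()].
#' @param target_spec target [static_cohort_spec()] (cohort = "target").
#' @param shared_edges integer edge indices planted in both cohorts; must be
#'   a subset of both specs' planted sets. NULL derives the intersection.
#' @return list with `reference`, `target` (both `static_cohort`) and
#'   `shared_edges`.
#' @export
gen_two_cohorts <- function(ref_spec, target_spec, shared_edges = NULL) {
  .stop_if(!inherits(ref_spec, "static_cohort_spec") ||
             !inherits(target_spec, "static_cohort_spec"),
           "both specs must come from static_cohort_spec()")
  ref_planted <- if (is.null(ref_spec$planted_edges)) integer(0)
                 else ref_spec$planted_edges$edge
  tgt_planted <- if (is.null(target_spec$planted_edges)) integer(0)
                 else target_spec$planted_edges$edge
  if (is.null(shared_edges)) {
    shared_edges <- intersect(ref_planted, tgt_planted)
  } else {
    .stop_if(!all(shared_edges %in% ref_planted) ||
               !all(shared_edges %in% tgt_planted),
             "shared_edges must be planted in both cohorts")
  }
  list(reference = gen_static_cohort(ref_spec),
       target = gen_static_cohort(target_spec),
       shared_edges = as.integer(shared_edges))
}
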