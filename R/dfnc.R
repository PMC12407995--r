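# Dynamic functional connectivity: tapered windows, windowed weighted
# correlations, occupancy rates, occupancy-symptom GLMs.

#' Tapered sliding-window weights
#'
#' Builds the taper by convolving a rectangular window of `length` samples
#' with a discrete Gaussian kernel of standard deviation `sigma` (support
#' +/- ceiling(3 sigma)), taking the central `length` samples of the full
#' convolution ("same" alignment) and normalizing to sum 1. The result is
#' strictly positive, symmetric about the window center, and tends to the
#' uniform window as `sigma -> 0`. With the defaults (length 20, sigma 3)
#' and a 2.36 s repetition time the window spans 47.2 s.
#'
#' @param length window length in TRs (>= 2; default 20).
#' @param sigma Gaussian standard deviation in TRs (> 0; default 3).
#' @return object of class `taper`: list with `length`, `sigma`, `weights`.
#' @export
make_taper <- function(length = 20, sigma = 3) {
  .stop_if(!.is_count(length) || length < 2, "length must be an integer >= 2")
  .stop_if(!.is_number(sigma) || sigma <= 0, "sigma must be positive")
  radius <- as.integer(ceiling(3 * sigma))
  x <- (-radius):radius
  g <- exp(-x^2 / (2 * sigma^2))
  w_full <- .conv_open(rep(1, length), g)
  w <- w_full[radius + seq_len(length)]
  w <- w / sum(w)
  structure(list(length = as.integer(length), sigma = sigma, weights = w),
            class = "taper")
}

#' @export
print.taper <- function(x, ...) {
  cat(sprintf("<taper> length %d TRs, sigma %g (edge/center weight ratio %.3f)\n",
              x$length, x$sigma, x$weights[1] / max(x$weights)))
  invisible(x)
}

#' Sliding-window start indices
#'
#' Half-open windows `[s, s + length)` (1-based starts); the window count is
#' `floor((T - length) / step) + 1`, so 229 timepoints with length 20 and
#' step 1 yield 210 windows.
#'
#' @param n_timepoints total timepoints T.
#' @param length window length in TRs.
#' @param step window step in TRs (default 1).
#' @return integer vector of start indices.
#' @export
sliding_windows <- function(n_timepoints, length = 20, step = 1) {
  .stop_if(!.is_count(n_timepoints), "n_timepoints must be a positive integer")
  .stop_if(!.is_count(length), "length must be a positive integer")
  .stop_if(!.is_count(step), "step must be a positive integer")
  .stop_if(n_timepoints < length,
           "time series shorter than the window (", n_timepoints,
           " < ", length, ")")
  seq.int(1L, as.integer(n_timepoints) - as.integer(length) + 1L,
          by = as.integer(step))
}

#' Windowed weighted correlation features
#'
#' Weighted Pearson correlation inside one window: weighted means,
#' covariances and variances under the taper weights, restricted to the
#' requested edges. With uniform weights this reduces exactly to the static
#' correlation of the window slice. Edges touching a component with zero
#' weighted variance in the window get an `NA` undefined marker.
#'
#' @param tc a `timecourse` or T x C matrix.
#' @param start window start index (1-based).
#' @param taper a [make_taper()] object (its length defines the window).
#' @param edges optional integer flat edge indices; default all edges.
#' @param idx optional [edge_index()].
#' @return named numeric vector of windowed correlations.
#' @export
weighted_fc <- function(tc, start, taper, edges = NULL, idx = NULL) {
  X <- if (inherits(tc, "timecourse")) tc$data else as.matrix(tc)
  .stop_if(!inherits(taper, "taper"), "taper must come from make_taper()")
  L <- taper$length
  .stop_if(!.is_count(start) || start + L - 1L > nrow(X),
           "window [", start, ", ", start + L - 1, "] out of bounds")
  idx <- idx %||% edge_index(ncol(X))
  edges <- if (is.null(edges)) seq_len(idx$n_edges) else as.integer(edges)
  w <- taper$weights
  S <- X[start:(start + L - 1L), , drop = FALSE]
  m <- colSums(S * w)
  Sc <- sweep(S, 2L, m)
  CV <- crossprod(Sc * w, Sc)          # sum_t w_t (x - m)(y - m)'
  v <- diag(CV)
  bad <- v <= 0
  denom <- sqrt(outer(v, v))
  R <- CV / denom
  if (any(bad)) {
    R[bad, ] <- NA_real_
    R[, bad] <- NA_real_
  }
  out <- R[cbind(idx$i[edges], idx$j[edges])]
  names(out) <- edge_names(idx)[edges]
  out
}

#' Dynamic connectivity tensor over a cohort
#'
#' Computes windowed weighted correlations for every subject on a designated
#' edge subset, via sliding weighted moments (a linear filter over the time
#' axis), which is algebraically identical to calling [weighted_fc()] per
#' window. Correlations are kept raw by default; `fisher_z = TRUE` applies
#' atanh before clustering.
#'
#' @param tcs list of `timecourse` objects (or T x C matrices).
#' @param edges integer flat edge indices defining the feature subset
#'   (e.g. the union of discovered edges).
#' @param window window length in TRs (default 20).
#' @param sigma taper Gaussian sd in TRs (default 3).
#' @param step window step in TRs (default 1).
#' @param fisher_z apply atanh to windowed correlations (default FALSE).
#' @return object of class `dfnc_tensor`: list with `data` (per subject
#'   W x E matrix), `subject_ids`, `starts`, `window`, `sigma`, `step`,
#'   `edges`, `n_components`.
#' @export
dfnc_tensor <- function(tcs, edges, window = 20, sigma = 3, step = 1,
                        fisher_z = FALSE) {
  .stop_if(!is.list(tcs) || length(tcs) == 0L, "tcs must be a nonempty list")
  mats <- lapply(tcs, function(tc) {
    if (inherits(tc, "timecourse")) tc$data else as.matrix(tc)
  })
  C <- ncol(mats[[1L]])
  .stop_if(!all(vapply(mats, ncol, 1L) == C),
           "all subjects must have the same component count")
  Tn <- nrow(mats[[1L]])
  .stop_if(!all(vapply(mats, nrow, 1L) == Tn),
           "all subjects must have the same scan length")
  idx <- edge_index(C)
  edges <- as.integer(edges)
  .stop_if(length(edges) == 0L || any(edges < 1L | edges > idx$n_edges),
           "invalid edge subset")
  taper <- make_taper(window, sigma)
  starts <- sliding_windows(Tn, window, step)
  w <- rev(taper$weights)   # filter() applies weights over the trailing lag
  at <- starts + window - 1L

  ia <- idx$i[edges]
  ib <- idx$j[edges]
  comps <- sort(unique(c(ia, ib)))
  pa <- match(ia, comps)
  pb <- match(ib, comps)

  slide <- function(M) {
    out <- stats::filter(M, w, method = "convolution", sides = 1)
    matrix(out[at, ], length(at), ncol(M))
  }
  data <- lapply(mats, function(X) {
    Xs <- X[, comps, drop = FALSE]
    Mw <- slide(Xs)                        # windowed weighted means
    Sq <- slide(Xs^2)                      # windowed weighted E[x^2]
    Sab <- slide(Xs[, pa, drop = FALSE] * Xs[, pb, drop = FALSE])
    Va <- Sq[, pa, drop = FALSE] - Mw[, pa, drop = FALSE]^2
    Vb <- Sq[, pb, drop = FALSE] - Mw[, pb, drop = FALSE]^2
    Cv <- Sab - Mw[, pa, drop = FALSE] * Mw[, pb, drop = FALSE]
    den <- Va * Vb
    R <- Cv / sqrt(den)
    R[den <= 0] <- NA_real_
    if (fisher_z) R <- atanh(pmin(pmax(R, -1 + 1e-15), 1 - 1e-15))
    colnames(R) <- edge_names(idx)[edges]
    R
  })
  ids <- vapply(seq_along(tcs), function(s) {
    if (inherits(tcs[[s]], "timecourse")) tcs[[s]]$subject_id
    else sprintf("S%04d", s)
  }, character(1))
  structure(
    list(data = data, subject_ids = ids, starts = starts,
         window = as.integer(window), sigma = sigma, step = as.integer(step),
         edges = edges, n_components = C),
    class = "dfnc_tensor"
  )
}

# stack a dfnc tensor into one matrix with a subject factor
.stack_dfnc <- function(dfnc) {
  if (inherits(dfnc, "dfnc_tensor")) {
    X <- do.call(rbind, dfnc$data)
    subj <- rep(dfnc$subject_ids, vapply(dfnc$data, nrow, 1L))
  } else {
    X <- as.matrix(dfnc)
    subj <- rep("S0001", nrow(X))
  }
  list(X = X, subject = subj)
}

#' Occupancy rates of a state vector
#'
#' The occupancy rate of state i is the number of windows assigned to that
#' state divided by the total number of windows; the k rates sum to 1 for
#' every subject.
#'
#' @param state_vector integer labels in 1..k over a subject's windows.
#' @param k number of states.
#' @return named numeric vector `OCR_1` .. `OCR_k`.
#' @export
occupancy <- function(state_vector, k) {
  .stop_if(length(state_vector) == 0L, "empty state vector")
  .stop_if(!.is_count(k), "k must be a positive integer")
  sv <- as.integer(state_vector)
  .stop_if(any(sv < 1L | sv > k), "state labels must lie in 1..k")
  setNames(tabulate(sv, nbins = k) / length(sv), paste0("OCR_", seq_len(k)))
}

#' Per-subject occupancy-rate table
#'
#' @param model a `state_model` from [cluster_states()].
#' @return subjects x k matrix of occupancy rates (rows sum to 1).
#' @export
occupancy_table <- function(model) {
  .stop_if(!inherits(model, "state_model"), "model must be a state_model")
  out <- t(vapply(model$state_vectors, occupancy, numeric(model$k),
                  k = model$k))
  rownames(out) <- names(model$state_vectors)
  out
}

#' Occupancy-symptom GLMs
#'
#' One covariate-adjusted GLM per state and symptom scale,
#' `symptom ~ covariates + OCR_i`. Occupancy rates are compositional (they
#' sum to 1), so each OCR enters its own model -- never all k together with
#' an intercept. BH-FDR is applied across the full k-states-by-scales
#' family.
#'
#' @param ocr subjects x k occupancy matrix (rownames = subject ids), e.g.
#'   from [occupancy_table()].
#' @param symptoms named numeric vector for one scale, or a data.frame of
#'   several scales with a `subject_id` column.
#' @param covariates covariate data.frame.
#' @param terms covariate terms (target-cohort default).
#' @return data.frame with scale, state, beta, se, t, p, q, partial_r, df.
#' @export
ocr_glm <- function(ocr, symptoms, covariates,
                    terms = c("age", "sex", "age2", "agexsex", "income",
                              "education_years", "site", "trauma_type")) {
  ocr <- as.matrix(ocr)
  k <- ncol(ocr)
  .stop_if(k < 2L, "occupancy regression needs k >= 2 states")
  if (is.data.frame(symptoms)) {
    .stop_if(!"subject_id" %in% names(symptoms),
             "symptom data.frame needs subject_id")
    scales <- setdiff(names(symptoms), "subject_id")
    sym_list <- lapply(scales, function(s) outcome_vector(symptoms, s))
    names(sym_list) <- scales
  } else {
    sym_list <- list(symptom = symptoms)
  }
  rows <- lapply(names(sym_list), function(sc) {
    al <- .align_cases(ocr, sym_list[[sc]], covariates, terms)
    X <- build_design(al$covariates, terms)$matrix
    st <- .edge_glm_engine(al$y, al$E, X, edge_as = "predictor")
    data.frame(scale = sc, state = seq_len(k), beta = st$beta, se = st$se,
               t = st$t, p = st$p, partial_r = st$partial_r, df = st$df,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  rownames(out) <- NULL
  out[, c("scale", "state", "beta", "se", "t", "p", "q", "partial_r", "df")]
}

#' Match estimated states to reference state patterns
#'
#' Finds the permutation of estimated centroids minimizing the total squared
#' distance to a reference pattern matrix (k x E, same feature order), by
#' exhaustive search over the k! permutations (k <= 8). Needed to compare
#' estimated occupancies with generator truth, since k-means labels are
#' arbitrary.
#'
#' @param centroids k x E estimated centroid matrix.
#' @param reference k x E reference pattern matrix.
#' @return integer vector `map` with `map[s]` = estimated state matching
#'   reference state s.
#' @export
match_states <- function(centroids, reference) {
  centroids <- as.matrix(centroids)
  reference <- as.matrix(reference)
  k <- nrow(reference)
  .stop_if(nrow(centroids) != k || ncol(centroids) != ncol(reference),
           "centroids and reference must have matching dimensions")
  .stop_if(k > 8L, "exhaustive matching supports k <= 8")
  D <- matrix(0, k, k)   # D[s, c] = squared distance reference s, centroid c
  for (s in seq_len(k)) {
    D[s, ] <- colSums((t(centroids) - reference[s, ])^2)
  }
  perms <- .permutations(k)
  cost <- apply(perms, 1L, function(p) sum(D[cbind(seq_len(k), p)]))
  as.integer(perms[which.min(cost), ])
}
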