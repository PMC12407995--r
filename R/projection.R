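#' Constrained out-of-sample projection of a discovered edge set
#'
#' Tests a reference-derived discovery set against a symptom measure in an
#' independent target cohort: each discovered edge is fit with the target
#' cohort's own covariate adjustment (`symptom ~ covariates + edge`) and
#' Benjamini-Hochberg FDR is applied across exactly the m = |discovery set|
#' tests for that symptom -- never across the full connectome. Restricting
#' the family this way preserves or increases rejections relative to
#' whole-connectome FDR at the same level on identical data.
#'
#' @param edge_table subjects x edges matrix for the target cohort.
#' @param discovery a `discovery_result` from the reference cohort, or an
#'   integer vector of flat edge indices (nonempty).
#' @param symptom numeric symptom vector named by subject id (e.g. a
#'   post-traumatic stress checklist total or an anxiety/depression T-score).
#' @param covariates target-cohort covariate data.frame.
#' @param alpha FDR level.
#' @param terms target covariate terms; the default matches a trauma-cohort
#'   adjustment: age, sex, age2, agexsex, income, education_years, site,
#'   trauma_type.
#' @param symptom_name label stored in the result.
#' @return object of class `projection_result`: `stats` data.frame (edge, i,
#'   j, beta, se, t, p, q, partial_r, df) over the discovered edges only,
#'   plus `m`, `alpha`, `symptom`, `n`.
#' @export
project_edges <- function(edge_table, discovery, symptom, covariates,
                          alpha = 0.05,
                          terms = c("age", "sex", "age2", "agexsex", "income",
                                    "education_years", "site", "trauma_type"),
                          symptom_name = NULL) {
  .stop_if(!.is_number(alpha) || alpha <= 0 || alpha > 1,
           "alpha must be in (0, 1]")
  sel <- .as_selected_edges(discovery)
  .stop_if(max(sel) > ncol(edge_table),
           "discovery set references edges beyond the target edge table")
  al <- .align_cases(edge_table, symptom, covariates, terms)
  X <- build_design(al$covariates, terms)$matrix
  E <- al$E[, sel, drop = FALSE]
  st <- .edge_glm_engine(al$y, E, X, edge_as = "predictor")
  .stop_if(any(st$constant), "constant edge among the projected set")
  C <- (1 + sqrt(1 + 8 * ncol(al$E))) / 2
  idx <- edge_index(as.integer(C))
  stats <- data.frame(edge = sel, i = idx$i[sel], j = idx$j[sel],
                      beta = st$beta, se = st$se, t = st$t, p = st$p,
                      q = bh_fdr(st$p), partial_r = st$partial_r, df = st$df)
  rownames(stats) <- NULL
  structure(
    list(stats = stats, m = length(sel), alpha = alpha,
         symptom = symptom_name %||% attr(symptom, "outcome_name") %||% "symptom",
         n = length(al$y)),
    class = "projection_result"
  )
}

#' @export
print.projection_result <- function(x, ...) {
  cat(sprintf("<projection> symptom '%s': %d/%d edges at q <= %g (n = %d)\n",
              x$symptom, sum(x$stats$q <= x$alpha), x$m, x$alpha, x$n))
  invisible(x)
}

#' Tabular report of significant projected edges
#'
#' Collects the significant rows (q <= alpha) of one or more projection
#' results into the standard reporting tuple: symptom, edge endpoints with
#' network and component labels, beta, SE, partial r, p, q and the
#' association-sign label. Rows are ordered by ascending p within symptom
#' (ties keep both rows). An empty significant set yields a zero-row frame
#' with the header intact.
#'
#' @param results a `projection_result` or list of them.
#' @param partition a `network_partition` for endpoint annotation.
#' @param alpha significance level; defaults to each result's own alpha.
#' @return data.frame, one row per significant (edge, symptom) pair.
#' @export
projection_report <- function(results, partition, alpha = NULL) {
  if (inherits(results, "projection_result")) results <- list(results)
  .stop_if(length(results) == 0L, "no projection results supplied")
  rows <- lapply(results, function(res) {
    a <- alpha %||% res$alpha
    st <- res$stats
    keep <- which(st$q <= a)
    keep <- keep[order(st$p[keep], st$edge[keep])]
    st <- st[keep, , drop = FALSE]
    if (nrow(st) == 0L) {
      return(data.frame(symptom = character(), edge = integer(),
                        component_i = integer(), component_j = integer(),
                        label_i = character(), label_j = character(),
                        network_i = character(), network_j = character(),
                        beta = numeric(), se = numeric(),
                        partial_r = numeric(), p = numeric(), q = numeric(),
                        direction = character(), stringsAsFactors = FALSE))
    }
    data.frame(symptom = res$symptom, edge = st$edge,
               component_i = st$i, component_j = st$j,
               label_i = partition$label[st$i],
               label_j = partition$label[st$j],
               network_i = partition$network[st$i],
               network_j = partition$network[st$j],
               beta = st$beta, se = st$se, partial_r = st$partial_r,
               p = st$p, q = st$q,
               direction = edge_sign_labels(st),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
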