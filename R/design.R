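#' Build a covariate design matrix
#'
#' Expands a covariate table into a full-rank numeric design matrix with the
#' intercept first. Derived terms are computed from base columns, never read
#' from disk: `age2` is age squared and `agexsex` is the age-by-sex
#' interaction (requiring a 0/1 sex code). Categorical covariates
#' (character/factor columns, e.g. site or trauma type) are reference-coded
#' with the alphabetically first level as reference, yielding L-1 indicator
#' columns. A rank-deficient design is an error naming the collinear
#' columns.
#'
#' @param covariates data.frame of per-subject covariates (no missing values;
#'   drop incomplete subjects first).
#' @param terms character vector of term names. Defaults to the reference
#'   cohort adjustment set: age, age2, sex, agexsex, site.
#' @return object of class `design_matrix`: list with `matrix` (n x p,
#'   intercept first), `columns`, `rank`, `n`, `terms`.
#' @examples
#' cv <- data.frame(age = c(50, 60, 70), sex = c(0, 1, 1),
#'                  site = c("a", "b", "a"))
#' build_design(cv, c("age", "age2", "sex", "agexsex", "site"))$columns
#' @export
build_design <- function(covariates,
                         terms = c("age", "age2", "sex", "agexsex", "site")) {
  .stop_if(!is.data.frame(covariates), "covariates must be a data.frame")
  .stop_if(nrow(covariates) < 2L, "need at least two subjects")
  .stop_if(length(terms) < 1L, "at least one term is required")

  get_num <- function(name) {
    .stop_if(!name %in% names(covariates),
             "covariate column missing: ", name)
    v <- covariates[[name]]
    if (is.factor(v) || is.character(v)) {
      f <- factor(v)
      .stop_if(nlevels(f) != 2L,
               "covariate '", name, "' must be numeric or two-level")
      v <- as.numeric(f) - 1
    }
    .stop_if(anyNA(v), "missing values in covariate '", name,
             "'; drop incomplete subjects before building the design")
    as.numeric(v)
  }

  blocks <- list()
  for (term in terms) {
    if (term == "age2") {
      blocks[[term]] <- matrix(get_num("age")^2, ncol = 1,
                               dimnames = list(NULL, "age2"))
    } else if (term %in% c("agexsex", "age_x_sex")) {
      blocks[[term]] <- matrix(get_num("age") * get_num("sex"), ncol = 1,
                               dimnames = list(NULL, "agexsex"))
    } else {
      .stop_if(!term %in% names(covariates),
               "covariate column missing: ", term)
      v <- covariates[[term]]
      .stop_if(anyNA(v), "missing values in covariate '", term,
               "'; drop incomplete subjects before building the design")
      if (is.numeric(v)) {
        blocks[[term]] <- matrix(as.numeric(v), ncol = 1,
                                 dimnames = list(NULL, term))
      } else {
        f <- factor(v)   # levels sort alphabetically; first is reference
        .stop_if(nlevels(f) < 2L,
                 "categorical covariate '", term, "' has a single level")
        mm <- stats::model.matrix(~f)[, -1, drop = FALSE]
        colnames(mm) <- paste0(term, ".", levels(f)[-1])
        blocks[[term]] <- mm
      }
    }
  }

  X <- cbind(`(Intercept)` = rep(1, nrow(covariates)),
             do.call(cbind, blocks))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  structure(
    list(matrix = X, columns = colnames(X), rank = qrX$rank,
         n = nrow(X), terms = terms),
    class = "design_matrix"
  )
}

# base covariate columns needed by a term vector
.base_columns <- function(terms) {
  unique(unlist(lapply(terms, function(t) {
    switch(t, age2 = "age", agexsex = c("age", "sex"),
           age_x_sex = c("age", "sex"), t)
  })))
}

# Align an edge (or OCR) matrix, outcome vector and covariate table on
# common subjects and drop rows with any missing required field; mirrors
# the exclusion of subjects with missing clinical information.
.align_cases <- function(E, outcome, covariates, terms) {
  .stop_if(is.null(rownames(E)), "edge matrix must have subject ids as rownames")
  y <- if (is.data.frame(outcome)) outcome_vector(outcome, names(outcome)[2L])
       else outcome
  .stop_if(is.null(names(y)), "outcome vector must be named by subject id")
  need <- .base_columns(terms)
  .stop_if(!all(need %in% names(covariates)),
           "covariate column(s) missing: ",
           paste(setdiff(need, names(covariates)), collapse = ", "))
  ids <- Reduce(intersect, list(rownames(E), names(y),
                                as.character(covariates$subject_id)))
  .stop_if(length(ids) == 0L, "no subjects shared by edges, outcome and covariates")
  cv <- covariates[match(ids, covariates$subject_id), , drop = FALSE]
  ok <- !is.na(y[ids]) & complete.cases(cv[, need, drop = FALSE])
  n_dropped <- sum(!ok) + (nrow(E) - length(ids))
  if (sum(!ok) > 0L) {
    message(sprintf("dropping %d subject(s) with missing outcome or covariates",
                    sum(!ok)))
  }
  ids <- ids[ok]
  .stop_if(length(ids) == 0L, "zero subjects left after missing-data drop")
  list(E = E[ids, , drop = FALSE], y = y[ids],
       covariates = cv[ok, , drop = FALSE], ids = ids, n_dropped = n_dropped)
}
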