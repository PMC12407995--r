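#' Read a per-subject component time-course matrix
#'
#' Reads a delimited text file (TSV, CSV, or whitespace-separated) holding
#' one scan's post-ICA component time courses, rows = timepoints, columns =
#' components. An optional single header row is detected and dropped.
#' Constant (zero-variance) columns are loaded but flagged degenerate and
#' reported in a warning, since no correlation is defined for them.
#'
#' @param path path to the file.
#' @param tr_seconds repetition time in seconds (default 2.36 s, under which
#'   a 20-sample window spans 47.2 s).
#' @param subject_id optional subject identifier; defaults to the file name
#'   without extension.
#' @return an object of class `timecourse`: list with `subject_id`, `data`
#'   (T x C numeric matrix), `tr_seconds`, and `degenerate` (integer vector
#'   of constant columns).
#' @export
read_timecourse <- function(path, tr_seconds = 2.36, subject_id = NULL) {
  .stop_if(!is.character(path) || length(path) != 1L || !file.exists(path),
           "time-course file not found: ", path)
  .stop_if(!.is_number(tr_seconds) || tr_seconds <= 0,
           "tr_seconds must be a positive number")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  .stop_if(length(lines) == 0L, "empty time-course file: ", path)

  sep <- if (grepl(",", lines[[1L]], fixed = TRUE)) "," else
         if (grepl("\t", lines[[1L]], fixed = TRUE)) "\t" else ""
  cells <- if (sep == "") {
    strsplit(trimws(lines), "[[:space:]]+")
  } else {
    lapply(strsplit(lines, sep, fixed = TRUE), trimws)
  }

  widths <- lengths(cells)
  header <- FALSE
  first <- suppressWarnings(as.numeric(cells[[1L]]))
  if (anyNA(first) && length(cells) > 1L) {
    header <- TRUE
    cells <- cells[-1L]
    widths <- widths[-1L]
  }
  if (length(unique(widths)) != 1L) {
    bad <- which(widths != widths[1L])[1L]
    stop(sprintf("ragged rows in %s: row %d has %d fields, expected %d",
                 path, bad + header, widths[bad], widths[1L]), call. = FALSE)
  }

  C <- widths[1L]
  T_ <- length(cells)
  vals <- suppressWarnings(as.numeric(unlist(cells, use.names = FALSE)))
  if (anyNA(vals)) {
    pos <- which(is.na(vals))[1L] - 1L
    r <- pos %/% C + 1L
    c <- pos %% C + 1L
    stop(sprintf("non-numeric value '%s' in %s at row %d, column %d",
                 cells[[r]][c], path, r + header, c), call. = FALSE)
  }
  mat <- matrix(vals, nrow = T_, ncol = C, byrow = TRUE)
  .stop_if(T_ < 2L || C < 2L,
           "a time-course matrix needs at least 2 timepoints and 2 components")

  degenerate <- which(apply(mat, 2L, function(x) var(x) == 0))
  if (length(degenerate)) {
    warning(sprintf("constant (degenerate) column(s) in %s: %s", path,
                    paste(degenerate, collapse = ", ")), call. = FALSE)
  }
  structure(
    list(subject_id = subject_id %||% sub("\\.[^.]*$", "", basename(path)),
         data = mat, tr_seconds = tr_seconds,
         degenerate = as.integer(degenerate)),
    class = "timecourse"
  )
}

#' @export
print.timecourse <- function(x, ...) {
  cat(sprintf("<timecourse> subject %s: %d timepoints x %d components (TR %.3g s)\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$tr_seconds))
  if (length(x$degenerate)) {
    cat("  degenerate columns:", paste(x$degenerate, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a time-course matrix as tab-separated text
#'
#' @param tc a `timecourse` object or numeric matrix.
#' @param path output path.
#' @export
write_timecourse <- function(tc, path) {
  mat <- if (inherits(tc, "timecourse")) tc$data else as.matrix(tc)
  utils::write.table(format(mat, digits = 17, trim = TRUE, scientific = TRUE),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a phenotype/covariate table
#'
#' CSV with a header; a `subject_id` column is mandatory and must be unique.
#' Derived model terms (age squared, age-by-sex) are never read from disk;
#' [build_design()] constructs them from the base columns.
#'
#' @param path path to the CSV file.
#' @return data.frame with `subject_id` as character.
#' @export
read_covariates <- function(path) {
  .stop_if(!file.exists(path), "covariate file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .stop_if(!"subject_id" %in% names(df),
           "covariate table must have a subject_id column: ", path)
  df$subject_id <- as.character(df$subject_id)
  .stop_if(anyDuplicated(df$subject_id) > 0L,
           "duplicated subject_id values in ", path)
  df
}

#' Extract a named outcome vector from a phenotype table
#'
#' @param pheno data.frame with a `subject_id` column.
#' @param column name of the outcome column.
#' @return numeric vector named by subject id.
#' @export
outcome_vector <- function(pheno, column) {
  .stop_if(!column %in% names(pheno), "no such outcome column: ", column)
  setNames(as.numeric(pheno[[column]]), as.character(pheno$subject_id))
}

#' Read a component-to-network partition table
#'
#' Two (or three) column CSV: `component_id`, `network`, optional `label`.
#' Every component 1..C must appear exactly once.
#'
#' @param path path to the CSV file.
#' @return data.frame of class `network_partition`, ordered by component.
#' @seealso [default_partition()] for the packaged 53-component fixture.
#' @export
read_partition <- function(path) {
  .stop_if(!file.exists(path), "partition file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .stop_if(!all(c("component_id", "network") %in% names(df)),
           "partition table needs component_id and network columns")
  df$component_id <- as.integer(df$component_id)
  df <- df[order(df$component_id), , drop = FALSE]
  C <- nrow(df)
  .stop_if(!identical(df$component_id, seq_len(C)),
           "partition must cover components 1..C exactly once")
  if (is.null(df$label)) df$label <- sprintf("%s_%d", df$network, df$component_id)
  rownames(df) <- NULL
  class(df) <- c("network_partition", "data.frame")
  df
}

#' Packaged 53-component network partition
#'
#' The shipped fixture assigns the 53 components of the standard template to
#' the seven canonical resting-state networks with the template's network
#' sizes (SC 5, AUD 2, SM 9, VIS 9, CC 17, DM 7, CB 4). Component labels in
#' the fixture are synthetic placeholders (`SC_1`, ...), not anatomical
#' names.
#'
#' @return a `network_partition` data.frame with 53 rows.
#' @export
default_partition <- function() {
  read_partition(system.file("extdata", "neuromark53_partition.csv",
                             package = "edgeproject", mustWork = TRUE))
}

#' Build a partition for an arbitrary component count
#'
#' Splits C components over the seven canonical networks in proportions
#' matching the 53-component template (largest-remainder rounding). Used by
#' the synthetic generators when `n_components != 53`.
#'
#' @param n_components number of components.
#' @return a `network_partition` data.frame.
#' @export
make_partition <- function(n_components) {
  .stop_if(!.is_count(n_components) || n_components < 2,
           "n_components must be an integer >= 2")
  base <- c(SC = 5, AUD = 2, SM = 9, VIS = 9, CC = 17, DM = 7, CB = 4)
  raw <- base / sum(base) * n_components
  cnt <- floor(raw)
  short <- n_components - sum(cnt)
  if (short > 0) {
    extra <- order(raw - cnt, decreasing = TRUE)[seq_len(short)]
    cnt[extra] <- cnt[extra] + 1
  }
  nets <- rep(names(cnt), times = cnt)
  df <- data.frame(component_id = seq_len(n_components), network = nets,
                   stringsAsFactors = FALSE)
  df$label <- ave(df$network, df$network,
                  FUN = function(x) sprintf("%s_%d", x, seq_along(x)))
  class(df) <- c("network_partition", "data.frame")
  df
}

#' Write a subjects-by-edges connectivity table as CSV
#'
#' One row per subject; columns `subject_id` then `e_<i>_<j>` in flat edge
#' order (1-based component labels). Values are written with 17 significant
#' digits so a write/read round trip reproduces doubles exactly.
#'
#' @param edges numeric matrix, subjects x edges, rownames = subject ids.
#' @param path output path.
#' @export
write_edge_table <- function(edges, path) {
  .stop_if(!is.matrix(edges) || !is.numeric(edges),
           "edges must be a numeric subjects x edges matrix")
  C <- (1 + sqrt(1 + 8 * ncol(edges))) / 2
  .stop_if(C != round(C), "column count is not C(C-1)/2 for any integer C")
  idx <- edge_index(as.integer(C))
  df <- data.frame(subject_id = rownames(edges) %||%
                     sprintf("S%04d", seq_len(nrow(edges))),
                   stringsAsFactors = FALSE)
  df[edge_names(idx)] <- as.data.frame(
    matrix(sprintf("%.17g", edges), nrow(edges), ncol(edges)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a subjects-by-edges connectivity table
#'
#' @param path CSV written by [write_edge_table()] (or matching its layout).
#' @return numeric matrix with subject ids as rownames and `e_i_j` colnames.
#' @export
read_edge_table <- function(path) {
  .stop_if(!file.exists(path), "edge table not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  .stop_if(!"subject_id" %in% names(df), "edge table must have subject_id")
  ids <- as.character(df$subject_id)
  mat <- as.matrix(df[setdiff(names(df), "subject_id")])
  storage.mode(mat) <- "double"
  rownames(mat) <- ids
  rng <- range(mat, na.rm = TRUE)
  .stop_if(rng[1] < -1 - 1e-8 || rng[2] > 1 + 1e-8,
           "edge table entries must be correlations in [-1, 1]")
  mat
}
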