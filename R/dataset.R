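#' Construct a binary-class expression dataset
#'
#' The central container of the package: a genes-by-samples matrix of
#' real-valued expression levels with a two-class label per sample.  Class 1
#' is the first element of `class_names` (conventionally the "normal" class)
#' and class 2 the second (the "tumor" class); the distinction matters
#' because the T-statistic and signal-to-noise scores are sign-sensitive.
#'
#' @param matrix numeric matrix, genes as rows, samples as columns.
#' @param gene_ids character vector of unique gene identifiers, one per row.
#' @param sample_ids character vector of unique sample identifiers, one per
#'   column.
#' @param labels character vector of class labels, one per sample; exactly
#'   two distinct tokens must be present, each with at least two samples.
#' @param class_names optional ordered pair fixing which label is class 1 and
#'   which is class 2; defaults to order of first appearance in `labels`.
#' @return an object of class `ExpressionDataset`.
#' @examples
#' m <- matrix(rnorm(12), nrow = 3)
#' ds <- expression_dataset(m, paste0("g", 1:3), paste0("s", 1:4),
#'                          c("A", "A", "B", "B"))
#' @export
expression_dataset <- function(matrix, gene_ids, sample_ids, labels,
                               class_names = NULL) {
  if (!is.matrix(matrix) || !is.numeric(matrix)) {
    stop("matrix must be a numeric matrix", call. = FALSE)
  }
  labels <- as.character(labels)
  if (is.null(class_names)) {
    class_names <- unique(labels)
  }
  ds <- structure(
    list(matrix = unname(matrix),
         gene_ids = as.character(gene_ids),
         sample_ids = as.character(sample_ids),
         labels = labels,
         class_names = as.character(class_names)),
    class = "ExpressionDataset")
  problems <- validate_dataset(ds)
  if (length(problems) > 0L) {
    stop("invalid dataset:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  }
  ds
}

#' Validate an expression dataset
#'
#' Checks every structural invariant of [expression_dataset()] and reports
#' violations as human-readable strings; it never raises.
#'
#' @param ds an `ExpressionDataset` (or a list with the same fields).
#' @return character vector of violation descriptions; empty iff valid.
#' @export
validate_dataset <- function(ds) {
  out <- character(0)
  if (!is.matrix(ds$matrix) || !is.numeric(ds$matrix)) {
    return("matrix is not a numeric matrix")
  }
  ng <- nrow(ds$matrix)
  ns <- ncol(ds$matrix)
  if (ng < 1L) out <- c(out, "dataset has no genes (0 rows)")
  if (length(ds$gene_ids) != ng) {
    out <- c(out, sprintf("gene_ids length (%d) != matrix rows (%d)",
                          length(ds$gene_ids), ng))
  }
  if (length(ds$sample_ids) != ns) {
    out <- c(out, sprintf("sample_ids length (%d) != matrix columns (%d)",
                          length(ds$sample_ids), ns))
  }
  if (length(ds$labels) != ns) {
    out <- c(out, sprintf("labels length (%d) != matrix columns (%d)",
                          length(ds$labels), ns))
  }
  dup <- unique(ds$gene_ids[duplicated(ds$gene_ids)])
  if (length(dup) > 0L) {
    out <- c(out, sprintf("duplicate gene id(s): %s",
                          paste(utils::head(dup, 5L), collapse = ", ")))
  }
  if (anyDuplicated(ds$sample_ids)) {
    out <- c(out, "duplicate sample ids")
  }
  classes <- unique(ds$labels)
  if (length(classes) != 2L) {
    out <- c(out, sprintf("expected exactly 2 classes, found %d (%s)",
                          length(classes),
                          paste(utils::head(classes, 5L), collapse = ", ")))
  } else {
    for (cl in classes) {
      n_cl <- sum(ds$labels == cl)
      if (n_cl < 2L) {
        out <- c(out, sprintf("class size < 2: class '%s' has %d sample(s)",
                              cl, n_cl))
      }
    }
    if (!setequal(ds$class_names, classes) ||
        length(ds$class_names) != 2L) {
      out <- c(out, "class_names do not match the labels present")
    }
  }
  bad <- which(!is.finite(ds$matrix), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    i <- bad[1L, 1L]
    j <- bad[1L, 2L]
    out <- c(out, sprintf(
      "%d non-finite expression value(s); first at gene '%s', sample '%s'",
      nrow(bad),
      if (i <= length(ds$gene_ids)) ds$gene_ids[i] else as.character(i),
      if (j <= length(ds$sample_ids)) ds$sample_ids[j] else as.character(j)))
  }
  out
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  n1 <- sum(x$labels == x$class_names[1L])
  n2 <- sum(x$labels == x$class_names[2L])
  cat(sprintf("ExpressionDataset: %d genes x %d samples (%s: %d, %s: %d)\n",
              nrow(x$matrix), ncol(x$matrix),
              x$class_names[1L], n1, x$class_names[2L], n2))
  invisible(x)
}

#' @export
dim.ExpressionDataset <- function(x) dim(x$matrix)

delim_char <- function(dialect) {
  switch(match.arg(dialect, c("tab", "csv")), tab = "\t", csv = ",")
}

#' Read a binary-class expression matrix from delimited text
#'
#' Expected layout: a header row of sample identifiers (optionally preceded
#' by a gene-id column header), then one row per gene whose first field is
#' the gene identifier.  Class labels come either from a `#labels` line
#' directly after the header, or from a two-column headerless companion file
#' (sample_id, label).
#'
#' @param path path to the matrix file.
#' @param dialect `"tab"` or `"csv"`.
#' @param labels path to a companion label file, or `NULL` to require an
#'   in-file `#labels` line.
#' @param impute `"none"` (reject missing values, the default) or `"mean"`
#'   (replace missing cells with the per-gene mean of observed values).
#' @param class_names optional ordered pair fixing class 1 / class 2.
#' @return an [expression_dataset()].
#' @export
read_expression_matrix <- function(path, dialect = c("tab", "csv"),
                                   labels = NULL,
                                   impute = c("none", "mean"),
                                   class_names = NULL) {
  dialect <- match.arg(dialect)
  impute <- match.arg(impute)
  sep <- delim_char(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("file has no data rows: ", path, call. = FALSE)

  header <- strsplit(lines[[1L]], sep, fixed = TRUE)[[1L]]
  body_start <- 2L
  label_line <- NULL
  if (length(lines) >= 2L && startsWith(lines[[2L]], "#labels")) {
    label_line <- strsplit(lines[[2L]], sep, fixed = TRUE)[[1L]][-1L]
    body_start <- 3L
  }
  body <- lines[seq.int(body_start, length(lines))]
  if (length(body) < 1L) stop("file has no data rows: ", path, call. = FALSE)

  rows <- strsplit(body, sep, fixed = TRUE)
  nfield <- length(rows[[1L]])
  if (nfield < 2L) {
    stop("parse error at row 1: fewer than 2 columns", call. = FALSE)
  }
  n_samples <- nfield - 1L
  # header may or may not carry a gene-id column header
  sample_ids <- if (length(header) == nfield) header[-1L]
                else if (length(header) == n_samples) header
                else stop(sprintf(
                  "header has %d fields but data rows have %d columns",
                  length(header), nfield), call. = FALSE)

  gene_ids <- character(length(rows))
  mat <- matrix(NA_real_, nrow = length(rows), ncol = n_samples)
  for (r in seq_along(rows)) {
    f <- rows[[r]]
    if (length(f) != nfield) {
      stop(sprintf("parse error at row %d: expected %d columns, found %d",
                   r, nfield, length(f)), call. = FALSE)
    }
    gene_ids[r] <- f[1L]
    vals <- suppressWarnings(as.numeric(f[-1L]))
    bad <- which(is.na(vals) & !(f[-1L] %in% c("NA", "NaN", "nan", "")))
    if (length(bad) > 0L) {
      stop(sprintf("parse error at row %d: non-numeric value '%s' in column %d",
                   r, f[-1L][bad[1L]], bad[1L] + 1L), call. = FALSE)
    }
    mat[r, ] <- vals
  }

  if (anyNA(mat)) {
    if (impute == "none") {
      bad <- which(is.na(mat), arr.ind = TRUE)
      stop(sprintf(
        "%d missing value(s); first at gene '%s', sample '%s' (use impute = \"mean\" to impute)",
        nrow(bad), gene_ids[bad[1L, 1L]], sample_ids[bad[1L, 2L]]),
        call. = FALSE)
    }
    for (r in which(rowSums(is.na(mat)) > 0L)) {
      miss <- is.na(mat[r, ])
      if (all(miss)) {
        stop(sprintf("gene '%s' has no observed values to impute from",
                     gene_ids[r]), call. = FALSE)
      }
      mat[r, miss] <- mean(mat[r, !miss])
    }
  }

  if (!is.null(labels)) {
    if (!file.exists(labels)) {
      stop("label file not found: ", labels, call. = FALSE)
    }
    lab_tab <- utils::read.table(labels, header = FALSE, sep = "",
                                 colClasses = "character",
                                 col.names = c("sample_id", "label"))
    idx <- match(sample_ids, lab_tab$sample_id)
    if (anyNA(idx)) {
      stop("label file is missing sample(s): ",
           paste(utils::head(sample_ids[is.na(idx)], 5L), collapse = ", "),
           call. = FALSE)
    }
    lab <- lab_tab$label[idx]
  } else if (!is.null(label_line)) {
    if (length(label_line) != n_samples) {
      stop(sprintf("#labels line has %d entries but there are %d samples",
                   length(label_line), n_samples), call. = FALSE)
    }
    lab <- label_line
  } else {
    stop("no labels: provide a companion label file or a '#labels' line",
         call. = FALSE)
  }

  expression_dataset(mat, gene_ids, sample_ids, lab,
                     class_names = class_names)
}

#' Write a binary-class expression matrix as delimited text
#'
#' Writes a header of sample ids, a `#labels` line, and one row per gene.
#' Values are printed with 17 significant digits so a read/write round trip
#' reproduces the matrix exactly.
#'
#' @param ds an [expression_dataset()].
#' @param path output path.
#' @param dialect `"tab"` or `"csv"`.
#' @param labels `"header"` to embed a `#labels` line (default) or a file
#'   path to write a two-column companion label file instead.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(ds, path, dialect = c("tab", "csv"),
                                    labels = "header") {
  dialect <- match.arg(dialect)
  problems <- validate_dataset(ds)
  if (length(problems) > 0L) {
    stop("refusing to write invalid dataset:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  sep <- delim_char(dialect)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(c("gene_id", ds$sample_ids), collapse = sep), con)
  if (identical(labels, "header")) {
    writeLines(paste(c("#labels", ds$labels), collapse = sep), con)
  } else {
    utils::write.table(
      data.frame(sample_id = ds$sample_ids, label = ds$labels),
      labels, sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
  }
  vals <- sprintf("%.17g", ds$matrix)
  dim(vals) <- dim(ds$matrix)
  body <- vapply(seq_len(nrow(vals)), function(r) {
    paste(c(ds$gene_ids[r], vals[r, ]), collapse = sep)
  }, character(1L))
  writeLines(body, con)
  invisible(path)
}

#' Per-class sample counts of a dataset
#' @param ds an [expression_dataset()].
#' @return named integer vector `c(n1, n2)` in class-name order.
#' @export
class_sizes <- function(ds) {
  stats::setNames(
    c(sum(ds$labels == ds$class_names[1L]),
      sum(ds$labels == ds$class_names[2L])),
    ds$class_names)
}
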