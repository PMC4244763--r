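#' Validate a biadjacency matrix
#'
#' A bipartite interaction network is represented throughout nestkit as a
#' plain numeric matrix with unique row and column names: rows are one class
#' of node, columns the other, and entries are non-negative interaction
#' weights (0 = no interaction).  `as_biadjacency()` coerces and validates
#' such a matrix; all other functions in the package call it on their input.
#'
#' @param x a numeric matrix, or something coercible to one (e.g. a
#'   data.frame with numeric columns).
#' @param labels if `x` carries no dimnames, labels `R1..Rn` / `C1..Cm` are
#'   generated when `labels = TRUE` (the default).
#' @return a numeric matrix with unique row and column names and all entries
#'   `>= 0`.
#' @export
as_biadjacency <- function(x, labels = TRUE) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x))
    stop_validation("input must be a numeric matrix")
  if (nrow(x) < 1L || ncol(x) < 1L)
    stop_validation("matrix must have at least one row and one column")
  if (anyNA(x))
    stop_validation("matrix contains missing values")
  neg <- which(x < 0, arr.ind = TRUE)
  if (nrow(neg) > 0L)
    stop_validation(sprintf("negative entry at row %d, column %d",
                            neg[1L, 1L], neg[1L, 2L]))
  if (is.null(rownames(x))) {
    if (!labels) stop_validation("matrix has no row labels")
    rownames(x) <- paste0("R", seq_len(nrow(x)))
  }
  if (is.null(colnames(x))) {
    if (!labels) stop_validation("matrix has no column labels")
    colnames(x) <- paste0("C", seq_len(ncol(x)))
  }
  if (anyDuplicated(rownames(x)))
    stop_validation("row labels are not unique")
  if (anyDuplicated(colnames(x)))
    stop_validation("column labels are not unique")
  x
}

#' Test whether a matrix is binary
#'
#' @param m a biadjacency matrix.
#' @return `TRUE` iff every entry is exactly 0 or 1.
#' @export
is_binary_matrix <- function(m) {
  all(m == 0 | m == 1)
}

#' Reduce a matrix to its presence/absence pattern
#'
#' @param m a biadjacency matrix.
#' @return the matrix with every nonzero entry replaced by 1.
#' @export
binarise <- function(m) {
  b <- (m != 0) * 1
  dimnames(b) <- dimnames(m)
  b
}

#' Read a biadjacency matrix from CSV
#'
#' Reads a comma-separated file holding a non-negative numeric matrix.  With
#' `has_headers = TRUE` the first row and the first column are taken as
#' column and row labels (both, matching the layout in which such incidence
#' tables are usually archived); with `has_headers = FALSE` the whole file is
#' numeric and labels `R1..`/`C1..` are generated.  The dialect is fixed:
#' comma separator, `.` decimal point, no quoting tricks; there is no
#' auto-detection.
#'
#' @param path path to a CSV file.
#' @param has_headers logical; does the file carry a header row *and* a
#'   header column?
#' @return a validated biadjacency matrix (see [as_biadjacency()]).
#' @export
read_biadjacency <- function(path, has_headers = TRUE) {
  if (!file.exists(path))
    stop_io(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop_validation("empty file")
  cells <- strsplit(lines, ",", fixed = TRUE)
  widths <- lengths(cells)
  if (length(unique(widths)) != 1L)
    stop_validation(sprintf(
      "ragged rows: line 1 has %d fields but line %d has %d",
      widths[1L], which(widths != widths[1L])[1L],
      widths[widths != widths[1L]][1L]))
  tab <- do.call(rbind, cells)
  tab <- trimws(tab)
  if (has_headers) {
    if (nrow(tab) < 2L || ncol(tab) < 2L)
      stop_validation("file too small to contain headers and a matrix body")
    row_labels <- tab[-1L, 1L]
    col_labels <- tab[1L, -1L]
    body <- tab[-1L, -1L, drop = FALSE]
  } else {
    row_labels <- paste0("R", seq_len(nrow(tab)))
    col_labels <- paste0("C", seq_len(ncol(tab)))
    body <- tab
  }
  num <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  bad <- which(is.na(num), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop_validation(sprintf("non-numeric cell at body row %d, column %d: '%s'",
                            bad[1L, 1L], bad[1L, 2L],
                            body[bad[1L, 1L], bad[1L, 2L]]))
  neg <- which(num < 0, arr.ind = TRUE)
  if (nrow(neg) > 0L)
    stop_validation(sprintf("negative entry at body row %d, column %d",
                            neg[1L, 1L], neg[1L, 2L]))
  dimnames(num) <- list(row_labels, col_labels)
  as_biadjacency(num)
}

#' Write a biadjacency matrix to CSV
#'
#' Inverse of [read_biadjacency()]: integer-valued entries are rendered
#' without a decimal point so that a read/write cycle is byte-faithful for
#' integer matrices.
#'
#' @param m a biadjacency matrix.
#' @param path output file path.
#' @param headers write row/column labels (default `TRUE`).
#' @return invisibly, `path`.
#' @export
write_biadjacency <- function(m, path, headers = TRUE) {
  m <- as_biadjacency(m)
  fmt <- function(v) {
    s <- vapply(v, function(x) {
      if (is.finite(x) && x == round(x)) sprintf("%d", as.integer(x))
      else format(x, trim = TRUE)
    }, character(1L))
    s
  }
  body <- apply(m, 1L, fmt)
  body <- if (is.matrix(body)) t(body) else matrix(body, nrow = nrow(m))
  lines <- apply(body, 1L, paste, collapse = ",")
  if (headers) {
    lines <- paste(rownames(m), lines, sep = ",")
    lines <- c(paste(c("", colnames(m)), collapse = ","), lines)
  }
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE)
  if (!ok) stop_io(sprintf("cannot write to %s", path))
  invisible(path)
}

#' Remove empty rows and columns
#'
#' Drops every all-zero row and column, keeping survivors in their original
#' relative order.  "Empty" means exactly zero; no epsilon is applied, since
#' entries encode presence/absence or recorded interaction strength, not
#' noisy measurements.  Idempotent.
#'
#' @param m a biadjacency matrix.
#' @return the stripped matrix.
#' @export
strip_empty <- function(m) {
  m <- as_biadjacency(m)
  keep_r <- rowSums(m != 0) > 0
  keep_c <- colSums(m != 0) > 0
  if (!any(keep_r) || !any(keep_c))
    stop_validation("matrix is entirely zero: nothing left after stripping")
  if (all(keep_r) && all(keep_c)) return(m)
  m[keep_r, keep_c, drop = FALSE]
}

# condition helpers: the CLI maps these classes to exit codes
stop_validation <- function(msg) {
  stop(structure(class = c("nk_validation_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1L))))
}

stop_io <- function(msg) {
  stop(structure(class = c("nk_io_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1L))))
}
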