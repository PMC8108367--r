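#' Read an expression matrix (genes x samples)
#'
#' Reads either a dense delimited table (first column = gene id, header row =
#' sample ids) or a MatrixMarket triplet file with sidecar gene / sample name
#' files. Regardless of the on-disk layout the in-memory convention is genes
#' in rows and samples in columns. Dense and sparse inputs with the same
#' content yield identical matrices.
#'
#' @param path Path to the matrix file.
#' @param fmt `"dense"` for a delimited table, `"mtx"` for MatrixMarket
#'   triplet format, or `"auto"` (default) to pick `"mtx"` for `.mtx` files.
#' @param genes_file,samples_file For `fmt = "mtx"`, one-identifier-per-line
#'   text files naming the rows and columns of the triplet matrix.
#' @param sep Field separator for dense files (default tab).
#' @return Numeric matrix with gene ids as rownames and sample ids as
#'   colnames; entries are validated to be non-negative and identifiers to be
#'   unique.
#' @export
read_expression <- function(path, fmt = c("auto", "dense", "mtx"),
                            genes_file = NULL, samples_file = NULL,
                            sep = "\t") {
  fmt <- match.arg(fmt)
  if (!file.exists(path)) stop_input("file not found: %s", path)
  if (fmt == "auto")
    fmt <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx" else "dense"
  if (fmt == "dense") {
    tab <- utils::read.table(path, header = TRUE, sep = sep,
                             check.names = FALSE, stringsAsFactors = FALSE,
                             row.names = NULL, comment.char = "")
    genes <- as.character(tab[[1L]])
    values <- as.matrix(tab[, -1L, drop = FALSE])
    storage.mode(values) <- "double"
    rownames(values) <- genes
  } else {
    if (is.null(genes_file) || is.null(samples_file))
      stop_input("MatrixMarket input requires gene and sample name files")
    m <- Matrix::readMM(path)
    genes <- readLines(genes_file)
    samples <- readLines(samples_file)
    if (nrow(m) != length(genes) || ncol(m) != length(samples))
      stop_input("matrix is %d x %d but name files list %d genes and %d samples",
                 nrow(m), ncol(m), length(genes), length(samples))
    values <- as.matrix(m)
    dimnames(values) <- list(genes, samples)
  }
  assert_expression_matrix(values, sprintf("expression matrix '%s'", basename(path)))
  values
}

#' Write an expression matrix as a dense delimited table
#'
#' @param expr Genes x samples numeric matrix with dimnames.
#' @param path Output path.
#' @param sep Field separator (default tab).
#' @export
write_expression <- function(expr, path, sep = "\t") {
  assert_expression_matrix(expr)
  write_named_matrix(expr, path, first_col = "gene_id", sep = sep)
}

# Shared writer: id column + numeric columns, fixed "%.10g" formatting.
write_named_matrix <- function(m, path, first_col, sep = "\t") {
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e) stop_input("cannot open '%s' for writing", path))
  on.exit(close(con))
  header <- paste(c(first_col, colnames(m)), collapse = sep)
  lines <- character(nrow(m))
  if (nrow(m) > 0) {
    body <- apply(m, 1L, function(r) paste(format_num(r), collapse = sep))
    lines <- paste(rownames(m), body, sep = if (ncol(m) > 0) sep else "")
  }
  writeLines(c(header, lines), con = con, sep = "\n")
  invisible(path)
}

#' Read / write spot coordinate tables
#'
#' Coordinate tables are delimited files with a header and columns
#' `sample_id`, `x`, `y` (platform units, e.g. pixels or micrometres).
#'
#' @param path File path.
#' @param sep Field separator.
#' @return `read_coordinates`: a data.frame with columns `sample_id`, `x`, `y`.
#' @export
read_coordinates <- function(path, sep = "\t") {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(tab) < 3L) stop_input("coordinate table needs 3 columns (id, x, y)")
  coords <- data.frame(sample_id = as.character(tab[[1L]]),
                       x = as.numeric(tab[[2L]]), y = as.numeric(tab[[3L]]),
                       stringsAsFactors = FALSE)
  assert_coordinates(coords)
}

#' @rdname read_coordinates
#' @param coords Data.frame with columns `sample_id`, `x`, `y`.
#' @export
write_coordinates <- function(coords, path, sep = "\t") {
  assert_coordinates(coords)
  con <- file(path, open = "wb"); on.exit(close(con))
  writeLines(c(paste(c("sample_id", "x", "y"), collapse = sep),
               paste(coords$sample_id, format_num(coords$x),
                     format_num(coords$y), sep = sep)), con = con, sep = "\n")
  invisible(path)
}

#' Read / write sample label tables (cell types or spot clusters)
#'
#' @param path File path.
#' @param sep Field separator.
#' @return `read_labels`: a data.frame with columns `sample_id`, `label`.
#' @export
read_labels <- function(path, sep = "\t") {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(tab) < 2L) stop_input("label table needs 2 columns (id, label)")
  labels <- data.frame(sample_id = as.character(tab[[1L]]),
                       label = as.character(tab[[2L]]),
                       stringsAsFactors = FALSE)
  assert_labels(labels)
}

#' @rdname read_labels
#' @param labels Data.frame with columns `sample_id`, `label`.
#' @export
write_labels <- function(labels, path, sep = "\t") {
  assert_labels(labels)
  con <- file(path, open = "wb"); on.exit(close(con))
  writeLines(c(paste(c("sample_id", "label"), collapse = sep),
               paste(labels$sample_id, labels$label, sep = sep)),
             con = con, sep = "\n")
  invisible(path)
}

#' Write and re-read cell-type composition matrices
#'
#' Compositions are spots x cell-types matrices of fractions on the simplex.
#' The on-disk form is a delimited table with one row per spot and one column
#' per cell type; values round-trip to at least 6 significant digits. A type
#' that never occurs keeps its (all-zero) column, and an empty composition
#' writes a header-only file.
#'
#' @param comp Spots x types numeric matrix with dimnames, or a
#'   [deconvolve()] result.
#' @param path Output path.
#' @param sep Field separator.
#' @export
write_composition <- function(comp, path, sep = "\t") {
  comp <- as_composition(comp)
  write_named_matrix(comp, path, first_col = "spot_id", sep = sep)
}

#' @rdname write_composition
#' @export
read_composition <- function(path, sep = "\t") {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE)
  values <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- as.character(tab[[1L]])
  values
}

# Accept either a bare spots x types matrix or a deconvolution fit.
as_composition <- function(comp) {
  if (inherits(comp, "spot_composition")) comp <- comp$fractions
  if (!is.matrix(comp) || !is.numeric(comp))
    stop_input("composition must be a numeric spots x types matrix")
  if (nrow(comp) > 0 && (is.null(rownames(comp)) || is.null(colnames(comp))))
    stop_input("composition must carry spot and cell-type identifiers")
  if (is.null(colnames(comp)))
    stop_input("composition must carry cell-type identifiers")
  comp
}

#' Read / write per-type marker gene sets
#'
#' Marker sets are stored as a two-column delimited table
#' (`cell_type`, `gene_id`).
#'
#' @param path File path.
#' @param sep Field separator.
#' @return `read_marker_sets`: a named list of character vectors.
#' @export
read_marker_sets <- function(path, sep = "\t") {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(tab) < 2L) stop_input("marker table needs 2 columns (cell_type, gene_id)")
  split(as.character(tab[[2L]]), as.character(tab[[1L]]))
}

#' @rdname read_marker_sets
#' @param sets Named list of character vectors of gene ids.
#' @export
write_marker_sets <- function(sets, path, sep = "\t") {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop_input("marker sets must be a named list")
  con <- file(path, open = "wb"); on.exit(close(con))
  lines <- unlist(lapply(names(sets), function(k) paste(k, sets[[k]], sep = sep)),
                  use.names = FALSE)
  writeLines(c(paste(c("cell_type", "gene_id"), collapse = sep), lines),
             con = con, sep = "\n")
  invisible(path)
}
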