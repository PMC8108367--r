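#' Library-size normalization
#'
#' Scales every column (cell or spot) to a common total so reference and
#' spatial profiles live on one scale — a prerequisite for the weighted
#' least-squares residual to be meaningful. All-zero columns are left
#' untouched with a warning.
#'
#' @param expr Genes x samples non-negative matrix.
#' @param scale Target column sum (default `1e4`).
#' @return Matrix of the same shape; every nonzero column sums to `scale`.
#' @export
normalize_library_size <- function(expr, scale = 1e4) {
  assert_expression_matrix(expr)
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0)
    stop_input("'scale' must be a single positive number")
  sums <- colSums(expr)
  if (all(sums == 0)) stop_input("all columns are zero; nothing to normalize")
  if (any(sums == 0)) {
    warning(sprintf("%d all-zero column(s) left unnormalized", sum(sums == 0)))
    sums[sums == 0] <- 1
  }
  sweep(expr, 2L, sums / scale, "/")
}

# Gini coefficient of a non-negative vector; 0 for a constant (or all-zero)
# vector, (n-1)/n for a one-hot vector.
gini_coefficient <- function(x) {
  n <- length(x)
  m <- mean(x)
  if (n < 2L || m == 0) return(0)
  xs <- sort(x)
  # mean absolute difference via the sorted-rank identity
  sum((2 * seq_len(n) - n - 1) * xs) / (n^2 * m)
}

#' Rank marker genes by a one-vs-all Gini specificity score
#'
#' For each gene the Gini coefficient of its mean expression across cell
#' types measures how concentrated the gene is in few types; this is
#' multiplied by a one-vs-rest detection contrast (fraction of in-type cells
#' expressing the gene minus the fraction of out-of-type cells expressing it)
#' to favour genes that are both specific and prevalent in the target type.
#' A gene with identical means in every type scores 0 for all types. This is
#' a self-contained specificity score, not a re-implementation of any
#' particular toolkit's internals.
#'
#' @param expr Genes x cells matrix, already library-size normalized.
#' @param labels Data.frame (`sample_id`, `label`) covering every cell.
#' @return Named list (one element per cell type) of data.frames with columns
#'   `gene_id` and `score`, sorted by decreasing score, ties broken by gene
#'   id.
#' @export
rank_markers_gini <- function(expr, labels) {
  assert_expression_matrix(expr)
  assert_labels(labels, colnames(expr))
  labs <- labels$label[match(colnames(expr), labels$sample_id)]
  types <- sort(unique(labs))
  if (length(types) < 2L) stop_input("need at least 2 cell types, got %d", length(types))
  counts <- table(labs)
  small <- names(counts)[counts < 2L]
  if (length(small))
    stop_input("cell type(s) with fewer than 2 cells: %s",
               paste(small, collapse = ", "))

  n_cells <- ncol(expr)
  type_means <- sapply(types, function(k) rowMeans(expr[, labs == k, drop = FALSE]))
  detected <- expr > 0
  pos_in <- sapply(types, function(k) rowSums(detected[, labs == k, drop = FALSE]))
  n_in <- as.numeric(counts[types])
  pos_total <- rowSums(detected)

  gini <- apply(type_means, 1L, gini_coefficient)
  out <- lapply(seq_along(types), function(j) {
    frac_in <- pos_in[, j] / n_in[j]
    frac_out <- (pos_total - pos_in[, j]) / (n_cells - n_in[j])
    score <- gini * (frac_in - frac_out)
    ord <- order(-score, rownames(expr))
    data.frame(gene_id = rownames(expr)[ord], score = score[ord],
               stringsAsFactors = FALSE, row.names = NULL)
  })
  names(out) <- types
  out
}

#' Build a cell-type signature matrix from a marker ranking
#'
#' The signature gene set is the union over types of each type's `top_n`
#' ranked genes; entry (g, k) is the mean expression of gene g over the cells
#' annotated as type k. Genes are returned in sorted id order. This matrix is
#' the design matrix of the deconvolution fit.
#'
#' @param expr Genes x cells reference matrix (same normalization as the
#'   spots to be deconvolved).
#' @param labels Data.frame (`sample_id`, `label`).
#' @param ranking Output of [rank_markers_gini()].
#' @param top_n Markers taken per type (default 100).
#' @return Signature-genes x cell-types matrix.
#' @export
build_signature <- function(expr, labels, ranking, top_n = 100L) {
  assert_expression_matrix(expr)
  assert_labels(labels, colnames(expr))
  if (!is.numeric(top_n) || top_n < 1) stop_input("'top_n' must be >= 1")
  sets <- marker_sets_from_ranking(ranking, top_n)
  universe <- sort(unique(unlist(sets, use.names = FALSE)))
  universe <- intersect(universe, rownames(expr))
  if (!length(universe)) stop_input("marker union is empty")
  labs <- labels$label[match(colnames(expr), labels$sample_id)]
  types <- sort(unique(labs))
  sig <- sapply(types, function(k)
    rowMeans(expr[universe, labs == k, drop = FALSE]))
  sig <- matrix(sig, nrow = length(universe),
                dimnames = list(universe, types))
  if (any(colSums(sig > 0) == 0))
    warning("signature column(s) with no positive entry")
  sig
}

marker_sets_from_ranking <- function(ranking, top_n) {
  if (!is.list(ranking) || is.null(names(ranking)))
    stop_input("ranking must be a named list as returned by rank_markers_gini()")
  lapply(ranking, function(df) utils::head(df$gene_id, top_n))
}

#' Extract the per-type marker gene sets used for enrichment
#'
#' Returns each type's `top_n` marker ids (the gene sets scored by PAGE).
#' Users who already have curated marker sets can pass them via `sets`, which
#' bypasses the ranking entirely and is returned unchanged.
#'
#' @param sig Signature matrix (defines the admissible gene universe).
#' @param ranking Output of [rank_markers_gini()]; ignored when `sets` given.
#' @param top_n Markers per type.
#' @param sets Optional user-supplied named list of gene id vectors.
#' @return Named list of character vectors, one per cell type.
#' @export
marker_sets_from_signature <- function(sig, ranking = NULL, top_n = 100L,
                                       sets = NULL) {
  if (!is.null(sets)) {
    if (is.null(names(sets))) stop_input("user marker sets must be named by cell type")
    return(sets)
  }
  if (is.null(ranking)) stop_input("either 'ranking' or 'sets' is required")
  out <- marker_sets_from_ranking(ranking, top_n)
  lapply(out, intersect, rownames(sig))
}
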