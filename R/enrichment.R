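#' Per-gene fold change against the across-spot mean
#'
#' Fold change of gene g at spot s is its expression divided by the mean of
#' that gene over all spots, so every row of the output averages to 1. Genes
#' with zero mean carry no contrast and are dropped with a warning. The plain
#' ratio is the default; `log2 = TRUE` instead returns
#' `log2((x + 1) / (mean + 1))` for users who prefer the classical
#' log-fold-change formulation of parametric gene-set enrichment.
#'
#' @param spot_expr Genes x spots matrix (>= 2 spots).
#' @param log2 Return log2 fold changes instead of ratios.
#' @return Genes x spots numeric matrix.
#' @export
fold_change <- function(spot_expr, log2 = FALSE) {
  assert_expression_matrix(spot_expr, "spot expression matrix")
  if (ncol(spot_expr) < 2L)
    stop_input("fold change needs >= 2 spots; the across-spot mean is not a contrast for 1 spot")
  mu <- rowMeans(spot_expr)
  if (any(mu == 0)) {
    warning(sprintf("dropping %d gene(s) with zero mean across spots", sum(mu == 0)))
    spot_expr <- spot_expr[mu > 0, , drop = FALSE]
    mu <- mu[mu > 0]
  }
  if (!nrow(spot_expr)) stop_input("no genes left after zero-mean filtering")
  if (log2) base::log2(sweep(spot_expr + 1, 1L, mu + 1, "/"))
  else sweep(spot_expr, 1L, mu, "/")
}

#' PAGE enrichment score per cell type and spot
#'
#' For each spot, a marker set of size m with mean fold change `S_m` is scored
#' against the background of all genes at that spot (mean `mu`, population
#' standard deviation `delta`):
#' `ES = (S_m - mu) * sqrt(m) / delta`.
#' Marker genes absent from the matrix are dropped (a warning fires when more
#' than half a set is lost); marker genes remain part of the background.
#' A spot whose fold changes are all identical (`delta = 0`) gets ES 0 with a
#' warning.
#'
#' @param fc Genes x spots fold-change matrix from [fold_change()].
#' @param marker_sets Named list of marker gene id vectors, one per type.
#' @return Cell-types x spots matrix of enrichment scores.
#' @export
page_score <- function(fc, marker_sets) {
  if (!is.matrix(fc) || !is.numeric(fc)) stop_input("'fc' must be a numeric matrix")
  if (is.null(names(marker_sets)) || !length(marker_sets))
    stop_input("'marker_sets' must be a non-empty named list")
  genes <- rownames(fc)
  kept <- lapply(marker_sets, intersect, genes)
  lost <- mapply(function(a, b) 1 - length(b) / max(length(a), 1L),
                 marker_sets, kept)
  if (any(lost > 0.5))
    warning(sprintf("more than half of the marker set lost for: %s",
                    paste(names(kept)[lost > 0.5], collapse = ", ")))
  empty <- lengths(kept) == 0L
  if (any(empty))
    stop_input("marker set(s) empty after intersecting with available genes: %s",
               paste(names(kept)[empty], collapse = ", "))

  n_genes <- nrow(fc)
  mu <- colMeans(fc)
  delta <- sqrt(colMeans(fc^2) - mu^2)    # population sd per spot
  delta[delta < 0] <- 0                    # guard fp round-off
  if (any(delta == 0))
    warning(sprintf("%d spot(s) with zero fold-change dispersion; ES set to 0",
                    sum(delta == 0)))
  es <- t(vapply(kept, function(set) {
    m <- length(set)
    s_m <- colMeans(fc[set, , drop = FALSE])
    out <- (s_m - mu) * sqrt(m) / ifelse(delta == 0, Inf, delta)
    out
  }, numeric(ncol(fc))))
  dimnames(es) <- list(names(kept), colnames(fc))
  es
}

#' Binarize an enrichment matrix into a per-spot cell-type mask
#'
#' A type is considered present at a spot when its enrichment score reaches
#' the cutoff (inclusive), ES >= 2 by default. A spot at which no type passes
#' would leave the deconvolution undefined, so its single top-scoring type is
#' kept instead and the spot is flagged.
#'
#' @param es Cell-types x spots score matrix from [page_score()].
#' @param cutoff Score threshold (default 2).
#' @return An `enrichment_matrix`: list with `es`, binary `mask` (same shape),
#'   `cutoff`, and logical per-spot `fallback` flags.
#' @export
binarize_enrichment <- function(es, cutoff = 2) {
  if (!is.matrix(es) || anyNA(es) || any(!is.finite(es)))
    stop_input("'es' must be a finite numeric matrix")
  mask <- (es >= cutoff) * 1L
  fallback <- colSums(mask) == 0L
  if (any(fallback)) {
    top <- apply(es[, fallback, drop = FALSE], 2L, which.max)
    mask[cbind(top, which(fallback))] <- 1L
  }
  structure(list(es = es, mask = mask, cutoff = cutoff,
                 fallback = stats::setNames(fallback, colnames(es))),
            class = "enrichment_matrix")
}

#' @export
print.enrichment_matrix <- function(x, ...) {
  cat(sprintf("enrichment_matrix: %d cell types x %d spots, cutoff %s\n",
              nrow(x$es), ncol(x$es), format(x$cutoff)))
  cat(sprintf("  types passing per spot: median %s; %d spot(s) used top-1 fallback\n",
              stats::median(colSums(x$mask)), sum(x$fallback)))
  invisible(x)
}

#' One-call enrichment: fold change, PAGE score, binarization
#'
#' @param spot_expr Genes x spots matrix.
#' @param marker_sets Named list of marker gene sets.
#' @param cutoff Binarization threshold (default 2).
#' @param log2 Use log2 fold changes (default FALSE).
#' @return An `enrichment_matrix` (see [binarize_enrichment()]).
#' @export
page_enrichment <- function(spot_expr, marker_sets, cutoff = 2, log2 = FALSE) {
  binarize_enrichment(page_score(fold_change(spot_expr, log2 = log2),
                                 marker_sets), cutoff)
}
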