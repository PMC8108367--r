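# Shared fixture builders. Everything is generated in code; no data files.

# Small genes x samples matrix with ids.
toy_expr <- function(values, genes = NULL, samples = NULL) {
  m <- as.matrix(values)
  rownames(m) <- genes %||% rownames(m) %||% sprintf("g%02d", seq_len(nrow(m)))
  colnames(m) <- samples %||% colnames(m) %||% sprintf("s%02d", seq_len(ncol(m)))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Reference with `mpt` planted markers per type: marker block of type k is
# elevated `effect`-fold. Returns expr, labels and the planted sets.
toy_reference <- function(n_types = 3L, n_genes = 30L, mpt = 5L,
                          cells_per_type = 10L, effect = 8, seed = 1L,
                          depth = 60) {
  # depth keeps background detection partial (~1 count/gene), the sparse
  # regime in which detection-contrast marker scores are informative
  sc <- synthetic_scenario(n_types = n_types, n_genes = n_genes,
                           markers_per_type = mpt,
                           n_cells_per_type = cells_per_type,
                           marker_effect = effect, ref_depth = depth,
                           seed = seed)
  synthesize_reference(sc)
}

# Random simplex vector.
rsimplex <- function(k) { x <- stats::rexp(k); x / sum(x) }

# Random full-rank-ish signature.
rsignature <- function(n_genes, n_types, seed = NULL) {
  gen <- function() {
    m <- matrix(stats::rexp(n_genes * n_types), n_genes, n_types,
                dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                sprintf("t%d", seq_len(n_types))))
    m
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# One-hot composition matrix from a label vector.
onehot_composition <- function(labels, spot_ids = NULL, types = NULL) {
  types <- types %||% sort(unique(labels))
  m <- outer(labels, types, `==`) * 1
  rownames(m) <- spot_ids %||% sprintf("sp%02d", seq_along(labels))
  colnames(m) <- types
  m
}

# Network built directly from an edge index matrix (rows = pairs).
manual_network <- function(n, edge_idx, ids = sprintf("sp%02d", seq_len(n))) {
  edges <- cbind(ids[edge_idx[, 1L]], ids[edge_idx[, 2L]])
  colnames(edges) <- c("from", "to")
  structure(list(spot_ids = ids, edges = edges, rule = "manual"),
            class = "spatial_network")
}

# Independent loop-based recomputation of the fractional assortativity:
# literal ordered-pair sums over a dense adjacency matrix.
assortativity_loop_oracle <- function(W, adj) {
  N <- nrow(W); K <- ncol(W)
  stopifnot(nrow(adj) == N)
  tot <- sum(adj)
  q <- numeric(K); a <- numeric(K)
  for (k in seq_len(K)) {
    s <- 0
    for (i in seq_len(N)) for (j in seq_len(N))
      s <- s + W[i, k] * W[j, k] * adj[i, j]
    q[k] <- s / tot
    a[k] <- mean(W[, k])
  }
  (sum(q) - sum(a^2)) / (1 - sum(a^2))
}

# Loop-based PAGE recomputation (population sd), the enrichment oracle.
page_loop_oracle <- function(fc, marker_sets) {
  K <- length(marker_sets); S <- ncol(fc)
  out <- matrix(NA_real_, K, S, dimnames = list(names(marker_sets), colnames(fc)))
  for (s in seq_len(S)) {
    col <- fc[, s]
    mu <- mean(col)
    delta <- sqrt(sum((col - mu)^2) / length(col))
    for (k in seq_len(K)) {
      genes <- intersect(marker_sets[[k]], rownames(fc))
      m <- length(genes)
      s_m <- mean(fc[genes, s])
      out[k, s] <- if (delta == 0) 0 else (s_m - mu) * sqrt(m) / delta
    }
  }
  out
}

# Weighted objective of a fraction vector.
wls_objective <- function(S, t, f, w = rep(1, nrow(S))) {
  sum(w * (as.numeric(S %*% f) - t)^2)
}
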