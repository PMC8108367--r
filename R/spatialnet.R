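#' Build a spatial neighbour network over spots
#'
#' Connects spots that are "immediately next to each other". Three neighbour
#' rules are offered: `grid` (default) connects pairs whose centre distance
#' is at most `param` times the minimum positive pairwise distance — with the
#' default `param = 1.05` this captures rook neighbours on square arrays and
#' the six neighbours of hexagonal arrays while excluding diagonals;
#' `radius` uses `param` as an absolute distance cutoff; `delaunay` keeps the
#' edges of the Delaunay triangulation (computed by the empty-circumcircle
#' characterization, suitable for the modest spot counts of a tissue
#' section).
#'
#' @param coords Spot coordinate data.frame (`sample_id`, `x`, `y`).
#' @param rule One of `"grid"`, `"radius"`, `"delaunay"`.
#' @param param Rule parameter: multiplier of the minimum spacing (`grid`,
#'   default 1.05) or absolute cutoff (`radius`, required).
#' @return A `spatial_network`: list with `spot_ids`, an `edges` matrix of
#'   unordered id pairs (no self-loops), and the `rule` used.
#' @export
build_neighbor_network <- function(coords, rule = c("grid", "radius", "delaunay"),
                                   param = NULL) {
  rule <- match.arg(rule)
  assert_coordinates(coords)
  n <- nrow(coords)
  if (n < 2L) stop_input("need at least 2 spots to build a network")
  xy <- cbind(coords$x, coords$y)
  dmat <- as.matrix(stats::dist(xy))
  pos <- dmat[upper.tri(dmat)]
  if (all(pos == 0)) stop_input("all spots coincide; no neighbour structure")

  if (rule == "grid") {
    if (is.null(param)) param <- 1.05
    cutoff <- param * min(pos[pos > 0])
    adj <- dmat <= cutoff & dmat > 0
  } else if (rule == "radius") {
    if (is.null(param)) stop_input("'radius' rule requires an absolute cutoff in 'param'")
    adj <- dmat <= param & dmat > 0
  } else {
    adj <- delaunay_adjacency(xy)
  }
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  edges <- cbind(coords$sample_id[idx[, 1L]], coords$sample_id[idx[, 2L]])
  colnames(edges) <- c("from", "to")
  structure(list(spot_ids = coords$sample_id, edges = edges, rule = rule),
            class = "spatial_network")
}

# Delaunay edges via the empty-circumcircle property: a triangle belongs to
# the triangulation iff no other point lies strictly inside its
# circumcircle. O(n^4) — fine for hundreds of spots, not for full slides.
delaunay_adjacency <- function(xy) {
  n <- nrow(xy)
  adj <- matrix(FALSE, n, n)
  if (n == 2L) { adj[1, 2] <- adj[2, 1] <- TRUE; return(adj) }
  for (i in seq_len(n - 2L)) for (j in (i + 1L):(n - 1L)) for (k in (j + 1L):n) {
    p <- xy[i, ]; q <- xy[j, ]; r <- xy[k, ]
    d <- 2 * (p[1] * (q[2] - r[2]) + q[1] * (r[2] - p[2]) + r[1] * (p[2] - q[2]))
    if (abs(d) < 1e-12) next                      # collinear triple
    p2 <- sum(p^2); q2 <- sum(q^2); r2 <- sum(r^2)
    ux <- (p2 * (q[2] - r[2]) + q2 * (r[2] - p[2]) + r2 * (p[2] - q[2])) / d
    uy <- (p2 * (r[1] - q[1]) + q2 * (p[1] - r[1]) + r2 * (q[1] - p[1])) / d
    rad2 <- (p[1] - ux)^2 + (p[2] - uy)^2
    others <- setdiff(seq_len(n), c(i, j, k))
    inside <- (xy[others, 1L] - ux)^2 + (xy[others, 2L] - uy)^2 < rad2 * (1 - 1e-12)
    if (!any(inside)) {
      adj[i, j] <- adj[j, i] <- TRUE
      adj[j, k] <- adj[k, j] <- TRUE
      adj[i, k] <- adj[k, i] <- TRUE
    }
  }
  adj
}

#' @export
print.spatial_network <- function(x, ...) {
  cat(sprintf("spatial_network (%s rule): %d spots, %d edges\n",
              x$rule, length(x$spot_ids), nrow(x$edges)))
  invisible(x)
}

#' Fractional-composition spatial assortativity
#'
#' Measures whether neighbouring spots hold similar cell-type mixtures.
#' With `w_k^i` the fraction of type k at spot i, `e_ij` the symmetric
#' adjacency indicator, and `N` the number of spots in the network:
#' `q_kk = sum_ij w_k^i w_k^j e_ij / sum_ij e_ij`, `a_k = mean_i w_k^i`, and
#' `Q = (sum_k q_kk - sum_k a_k^2) / (1 - sum_k a_k^2)`.
#' The ordered-pair double counting cancels in the ratio, so undirected
#' edges are used internally. With one-hot (binary) compositions this is
#' exactly Newman's discrete assortativity coefficient of the labelled
#' graph. Spots without neighbours still enter `a_k` but contribute nothing
#' to `q_kk`.
#'
#' @param comp Spots x types composition matrix (rows on the simplex)
#'   covering at least the network's spots.
#' @param net A `spatial_network` from [build_neighbor_network()].
#' @return An `assortativity_result`: list with `Q`, per-type `a_k` and
#'   `q_kk`, and `n_edges`.
#' @export
assortativity <- function(comp, net) {
  comp <- as_composition(comp)
  if (!inherits(net, "spatial_network")) stop_input("'net' must be a spatial_network")
  miss <- setdiff(net$spot_ids, rownames(comp))
  if (length(miss))
    stop_input("composition missing %d network spot(s), e.g. %s", length(miss),
               paste(utils::head(miss, 3L), collapse = ", "))
  W <- comp[net$spot_ids, , drop = FALSE]
  if (any(W < -1e-9) || any(abs(rowSums(W) - 1) > 1e-6))
    stop_input("composition rows must lie on the simplex")
  if (nrow(net$edges) == 0L) stop_input("network has no edges")
  a <- colMeans(W)
  i <- match(net$edges[, 1L], net$spot_ids)
  j <- match(net$edges[, 2L], net$spot_ids)
  # ordered-pair sums: each undirected edge counts twice top and bottom
  q_kk <- colSums(W[i, , drop = FALSE] * W[j, , drop = FALSE]) / nrow(net$edges)
  denom <- 1 - sum(a^2)
  if (abs(denom) < 1e-12)
    stop_numeric("assortativity undefined: a single cell type occupies every spot")
  structure(list(Q = (sum(q_kk) - sum(a^2)) / denom,
                 a_k = a, q_kk = q_kk, n_edges = nrow(net$edges)),
            class = "assortativity_result")
}

#' @export
print.assortativity_result <- function(x, ...) {
  cat(sprintf("assortativity Q = %.4f over %d edges\n", x$Q, x$n_edges))
  invisible(x)
}

#' Assortativity across samples grouped by condition or stage
#'
#' Computes Q per sample and averages within groups, e.g. developmental
#' stages of a tissue series.
#'
#' @param comps List of composition matrices, one per sample.
#' @param nets List of matching `spatial_network`s.
#' @param group_labels Character vector assigning each sample to a group.
#' @return List with `samples` (data.frame `sample`, `group`, `Q`) and
#'   `group_means` (named vector).
#' @export
assortativity_trend <- function(comps, nets, group_labels) {
  if (length(comps) != length(nets) || length(comps) != length(group_labels))
    stop_input("'comps', 'nets' and 'group_labels' must have equal length")
  if (!length(comps)) stop_input("no samples supplied")
  qs <- vapply(seq_along(comps), function(i) assortativity(comps[[i]], nets[[i]])$Q,
               numeric(1L))
  ids <- if (!is.null(names(comps))) names(comps)
         else sprintf("sample_%d", seq_along(comps))
  samples <- data.frame(sample = ids, group = as.character(group_labels), Q = qs,
                        stringsAsFactors = FALSE)
  list(samples = samples,
       group_means = tapply(samples$Q, samples$group, mean))
}
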