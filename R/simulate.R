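#' Coarse-grain single-cell-resolution spatial data into pseudo-spots
#'
#' Cells are binned into square spot-like regions of side `bin_size`
#' (half-open intervals `[k*b, (k+1)*b)` on each axis, origin at the minimum
#' coordinate of the field of view), their expression is aggregated per bin,
#' and the exact cell-type mixture of each bin becomes the ground-truth
#' composition. This turns data with known per-cell annotations into a
#' deconvolution benchmark with known answers.
#'
#' @param expr Genes x cells matrix.
#' @param coords Per-cell coordinate data.frame (`sample_id`, `x`, `y`).
#' @param labels Per-cell type annotations (`sample_id`, `label`).
#' @param bin_size Side of the square bin, in coordinate units.
#' @param aggregate `"sum"` (aggregate transcript counts; default) or
#'   `"mean"` (average expression over member cells).
#' @param min_cells Bins with fewer cells are dropped (default 1, i.e. only
#'   empty bins are dropped).
#' @return List with `spot_expr` (genes x spots), `spot_coords` (bin
#'   centers), `truth` (spots x types, rows are exact rationals
#'   cells-of-type / cells-in-bin), and `cells_per_spot`.
#' @export
coarse_grain <- function(expr, coords, labels, bin_size,
                         aggregate = c("sum", "mean"), min_cells = 1L) {
  aggregate <- match.arg(aggregate)
  assert_expression_matrix(expr)
  assert_coordinates(coords)
  assert_labels(labels, colnames(expr))
  if (!is.numeric(bin_size) || bin_size <= 0) stop_input("'bin_size' must be > 0")
  cells <- colnames(expr)
  miss <- setdiff(cells, coords$sample_id)
  if (length(miss))
    stop_input("missing coordinates for %d cell(s), e.g. %s", length(miss),
               paste(utils::head(miss, 3L), collapse = ", "))
  idx <- match(cells, coords$sample_id)
  x <- coords$x[idx]; y <- coords$y[idx]
  ix <- as.integer(floor((x - min(x)) / bin_size))
  iy <- as.integer(floor((y - min(y)) / bin_size))
  bin <- sprintf("spot_%d_%d", ix, iy)

  keep_bins <- names(which(table(bin) >= min_cells))
  keep <- bin %in% keep_bins
  expr <- expr[, keep, drop = FALSE]
  bin <- bin[keep]
  labs <- labels$label[match(colnames(expr), labels$sample_id)]
  spots <- sort(unique(bin))
  types <- sort(unique(labels$label))

  agg_fun <- if (aggregate == "sum") rowSums else rowMeans
  spot_expr <- sapply(spots, function(b) agg_fun(expr[, bin == b, drop = FALSE]))
  spot_expr <- matrix(spot_expr, nrow = nrow(expr),
                      dimnames = list(rownames(expr), spots))
  counts <- table(factor(bin, levels = spots), factor(labs, levels = types))
  cells_per_spot <- as.integer(rowSums(counts))
  truth <- as.matrix(sweep(unclass(counts), 1L, cells_per_spot, "/"))
  dimnames(truth) <- list(spots, types)

  parts <- do.call(rbind, strsplit(sub("^spot_", "", spots), "_"))
  cx <- min(x) + (as.numeric(parts[, 1L]) + 0.5) * bin_size
  cy <- min(y) + (as.numeric(parts[, 2L]) + 0.5) * bin_size
  list(spot_expr = spot_expr,
       spot_coords = data.frame(sample_id = spots, x = cx, y = cy,
                                stringsAsFactors = FALSE),
       truth = truth,
       cells_per_spot = stats::setNames(cells_per_spot, spots))
}

#' Define a synthetic benchmark scenario
#'
#' Describes a fully synthetic tissue: a reference of `n_types` cell types
#' whose `markers_per_type` disjoint marker genes are elevated
#' `marker_effect`-fold over background, plus spots generated as Poisson
#' mixtures of the type profiles. Defaults emulate a small cortex-like
#' benchmark: 6 cell types, 60 markers each at 10-fold elevation, 100 spots
#' of about 7 cells with a sequencing depth of 2000 transcripts.
#'
#' @param n_types,n_genes,markers_per_type,n_cells_per_type Reference shape.
#' @param n_spots Number of synthetic spots.
#' @param cells_per_spot Cells mixed into each spot (sets the resolution of
#'   the ground-truth fractions).
#' @param max_types_per_spot Upper bound on distinct types per spot; small
#'   values create the presence/absence structure of real tissue.
#' @param marker_effect Fold elevation of a marker in its own type.
#' @param depth Expected transcript count per spot (Poisson noise model).
#' @param ref_depth Expected transcript count per reference cell.
#' @param seed Integer seed; every draw in the scenario flows from it.
#' @return A validated `synthetic_scenario` list.
#' @export
synthetic_scenario <- function(n_types = 6L, n_genes = 1000L,
                               markers_per_type = 60L, n_cells_per_type = 50L,
                               n_spots = 100L, cells_per_spot = 7L,
                               max_types_per_spot = 3L, marker_effect = 10,
                               depth = 2000L, ref_depth = 2000L, seed = 1L) {
  sc <- list(n_types = as.integer(n_types), n_genes = as.integer(n_genes),
             markers_per_type = as.integer(markers_per_type),
             n_cells_per_type = as.integer(n_cells_per_type),
             n_spots = as.integer(n_spots),
             cells_per_spot = as.integer(cells_per_spot),
             max_types_per_spot = as.integer(max_types_per_spot),
             marker_effect = as.numeric(marker_effect),
             depth = as.numeric(depth), ref_depth = as.numeric(ref_depth),
             seed = as.integer(seed))
  if (any(unlist(sc[c("n_types", "n_genes", "markers_per_type",
                      "n_cells_per_type", "n_spots", "cells_per_spot",
                      "max_types_per_spot")]) < 1L))
    stop_input("all scenario counts must be positive")
  if (sc$n_genes < sc$n_types * sc$markers_per_type)
    stop_input("n_genes too small for %d disjoint marker sets of %d",
               sc$n_types, sc$markers_per_type)
  if (sc$marker_effect < 0 || sc$depth < 0 || sc$ref_depth <= 0)
    stop_input("effects and depths must be non-negative (ref_depth positive)")
  structure(sc, class = "synthetic_scenario")
}

#' Synthesize an annotated single-cell reference
#'
#' Each type's expected profile is flat background with its own disjoint
#' marker block elevated `marker_effect`-fold, scaled to `ref_depth` expected
#' transcripts per cell; counts are Poisson draws. `marker_effect = 1` gives
#' a null reference with no type structure.
#'
#' @param sc A [synthetic_scenario()].
#' @return List with `expr` (genes x cells counts), `labels`, `marker_sets`
#'   (the planted truth), and `profiles` (genes x types expected values).
#' @export
synthesize_reference <- function(sc) {
  stopifnot(inherits(sc, "synthetic_scenario"))
  genes <- sprintf("g%04d", seq_len(sc$n_genes))
  types <- sprintf("type_%d", seq_len(sc$n_types))
  marker_sets <- stats::setNames(lapply(seq_len(sc$n_types), function(k)
    genes[((k - 1L) * sc$markers_per_type + 1L):(k * sc$markers_per_type)]),
    types)
  profiles <- sapply(seq_len(sc$n_types), function(k) {
    p <- rep(1, sc$n_genes)
    p[((k - 1L) * sc$markers_per_type + 1L):(k * sc$markers_per_type)] <- sc$marker_effect
    p / sum(p) * sc$ref_depth
  })
  dimnames(profiles) <- list(genes, types)
  n_cells <- sc$n_types * sc$n_cells_per_type
  cell_type <- rep(types, each = sc$n_cells_per_type)
  cells <- sprintf("cell_%04d", seq_len(n_cells))
  expr <- with_seed(sc$seed, {
    m <- vapply(cell_type, function(k) stats::rpois(sc$n_genes, profiles[, k]),
                numeric(sc$n_genes))
    m
  })
  dimnames(expr) <- list(genes, cells)
  list(expr = expr,
       labels = data.frame(sample_id = cells, label = cell_type,
                           stringsAsFactors = FALSE),
       marker_sets = marker_sets, profiles = profiles)
}

#' Draw ground-truth spot compositions with presence/absence structure
#'
#' Each spot holds `cells_per_spot` cells drawn from a small random subset of
#' types (at most `max_types`), so fractions are exact rationals with
#' denominator `cells_per_spot` and most types are absent from most spots —
#' the regime in which enrichment-based type pre-selection matters.
#'
#' @param n_spots Number of spots.
#' @param type_ids Character vector of type names.
#' @param cells_per_spot Cells per spot.
#' @param max_types Maximum distinct types per spot.
#' @param seed Integer seed.
#' @return Spots x types composition matrix (rows sum to 1).
#' @export
random_compositions <- function(n_spots, type_ids, cells_per_spot = 7L,
                                max_types = 3L, seed = 1L) {
  K <- length(type_ids)
  if (K < 1L) stop_input("need at least one type")
  comp <- with_seed(seed, {
    t(vapply(seq_len(n_spots), function(i) {
      k <- sample.int(min(max_types, K), 1L)
      chosen <- sample.int(K, k)
      counts <- stats::rmultinom(1L, cells_per_spot, rep(1 / k, k))[, 1L]
      out <- numeric(K)
      out[chosen] <- counts / cells_per_spot
      out
    }, numeric(K)))
  })
  dimnames(comp) <- list(sprintf("spot_%03d", seq_len(n_spots)), type_ids)
  comp
}

#' Synthesize spot expression from type profiles and known compositions
#'
#' The expected spot profile is the composition-weighted mixture of the
#' per-type expected profiles, rescaled to `depth` expected transcripts;
#' observed counts are Poisson. Spots are laid out row-major on a unit grid
#' so that neighbourhood structure is defined for spatial statistics.
#'
#' @param profiles Genes x types matrix of expected per-type profiles.
#' @param compositions Spots x types matrix on the simplex.
#' @param depth Expected total transcripts per spot (0 gives all-zero spots).
#' @param seed Integer seed.
#' @return List with `expr` (genes x spots counts) and `coords`.
#' @export
synthesize_spots <- function(profiles, compositions, depth, seed = 1L) {
  if (!is.matrix(profiles) || !is.matrix(compositions))
    stop_input("'profiles' and 'compositions' must be matrices")
  if (!setequal(colnames(profiles), colnames(compositions)))
    stop_input("profile and composition type ids differ")
  if (any(compositions < 0) ||
      any(abs(rowSums(compositions) - 1) > 1e-6))
    stop_input("compositions must lie on the simplex")
  compositions <- compositions[, colnames(profiles), drop = FALSE]
  mean_expr <- profiles %*% t(compositions)          # genes x spots
  cs <- colSums(mean_expr)
  cs[cs == 0] <- 1
  lambda <- sweep(mean_expr, 2L, cs / max(depth, 0), "/")
  if (depth == 0) lambda[] <- 0
  expr <- with_seed(seed,
    matrix(stats::rpois(length(lambda), lambda), nrow = nrow(lambda)))
  dimnames(expr) <- list(rownames(profiles), rownames(compositions))
  n <- nrow(compositions)
  side <- ceiling(sqrt(n))
  coords <- data.frame(sample_id = rownames(compositions),
                       x = (seq_len(n) - 1L) %% side,
                       y = (seq_len(n) - 1L) %/% side,
                       stringsAsFactors = FALSE)
  list(expr = expr, coords = coords)
}

#' Generate a complete synthetic benchmark bundle
#'
#' Runs [synthesize_reference()], [random_compositions()] and
#' [synthesize_spots()] with seeds derived from the scenario seed, returning
#' everything the benchmark pipeline consumes.
#'
#' @param sc A [synthetic_scenario()].
#' @return List: `reference` (expr, labels, marker_sets, profiles), `truth`
#'   composition matrix, `spot_expr`, `spot_coords`.
#' @export
synthesize_benchmark <- function(sc) {
  stopifnot(inherits(sc, "synthetic_scenario"))
  ref <- synthesize_reference(sc)
  truth <- random_compositions(sc$n_spots, colnames(ref$profiles),
                               cells_per_spot = sc$cells_per_spot,
                               max_types = sc$max_types_per_spot,
                               seed = sc$seed + 1L)
  spots <- synthesize_spots(ref$profiles, truth, sc$depth, seed = sc$seed + 2L)
  list(reference = ref, truth = truth, spot_expr = spots$expr,
       spot_coords = spots$coords)
}
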