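#' Solver configuration for dampened weighted least squares
#'
#' @param damping_candidates Strictly increasing positive candidates for the
#'   damping constant d; default `2^(0:13)`.
#' @param max_iter Maximum reweighting iterations per solve (default 100).
#' @param tol Convergence tolerance on `max |f_new - f_old|` (default 1e-8).
#' @param min_frequency Types estimated below this fraction are removed
#'   before the second deconvolution round (default 0.02; strict `<`).
#' @param cv_folds Number of half-gene subsamples used to cross-validate d
#'   (default 10).
#' @param seed Integer seed controlling every random draw in the solver
#'   (cross-validation subsampling, k-means fallback clustering).
#' @return A validated `solver_config` list.
#' @export
solver_config <- function(damping_candidates = 2^(0:13), max_iter = 100L,
                          tol = 1e-8, min_frequency = 0.02, cv_folds = 10L,
                          seed = 1L) {
  if (any(damping_candidates <= 0) || is.unsorted(damping_candidates, strictly = TRUE))
    stop_input("damping candidates must be positive and strictly increasing")
  if (min_frequency <= 0 || min_frequency >= 1)
    stop_input("'min_frequency' must lie in (0, 1)")
  if (max_iter < 1L || cv_folds < 1L || tol <= 0)
    stop_input("invalid solver configuration")
  structure(list(damping_candidates = as.numeric(damping_candidates),
                 max_iter = as.integer(max_iter), tol = tol,
                 min_frequency = min_frequency, cv_folds = as.integer(cv_folds),
                 seed = as.integer(seed)),
            class = "solver_config")
}

# Active-set solver for  min_f  f' D f - 2 d' f   s.t.  sum(f) = 1, f >= 0,
# with D positive semidefinite. Iterates stay primal-feasible; equality-
# constrained subproblems are solved through their KKT system, falling back
# to a pseudoinverse when the free-set system is singular (rank-deficient
# signatures stay solvable because the QP is convex).
simplex_qp <- function(D, d) {
  K <- length(d)
  if (K == 1L) return(list(f = 1, rank_deficient = FALSE))
  x <- rep(1 / K, K)
  free <- rep(TRUE, K)
  rank_deficient <- FALSE

  solve_eqp <- function(free) {
    nf <- sum(free)
    kkt <- rbind(cbind(2 * D[free, free, drop = FALSE], rep(1, nf)),
                 c(rep(1, nf), 0))
    rhs <- c(2 * d[free], 1)
    sol <- tryCatch(solve(kkt, rhs), error = function(e) {
      rank_deficient <<- TRUE
      as.numeric(MASS::ginv(kkt) %*% rhs)
    })
    list(y = sol[seq_len(nf)], lambda = sol[nf + 1L])
  }

  for (iter in seq_len(50L * K)) {
    sub <- solve_eqp(free)
    y <- numeric(K); y[free] <- sub$y
    if (all(y[free] >= -1e-10)) {
      x <- pmax(y, 0); x <- x / sum(x)
      if (all(free)) break
      # dual feasibility of the clamped coordinates
      # moving mass from a free coordinate (gradient -lambda there) to a
      # clamped one must not decrease the objective: g_i + lambda >= 0
      g <- 2 * (as.numeric(D %*% x) - d)
      mu <- g[!free] + sub$lambda
      if (min(mu) >= -1e-9) break
      release <- which(!free)[which.min(mu)]
      free[release] <- TRUE
    } else {
      # step from x toward y until the first coordinate hits zero
      idx <- which(free & y < x & y < 0)
      alpha <- min(x[idx] / (x[idx] - y[idx]))
      x <- x + alpha * (y - x)
      x[x < 1e-14] <- 0
      block <- idx[which.min(x[idx])]
      x[block] <- 0
      free[block] <- FALSE
      if (!any(free)) { free[which.max(d)] <- TRUE }
      x <- x / sum(x)
    }
  }
  list(f = x, rank_deficient = rank_deficient)
}

#' Constrained weighted least squares on the probability simplex
#'
#' Solves `argmin_f sum_g w_g ((S f)_g - t_g)^2` subject to `f >= 0` and
#' `sum(f) = 1` with an exact active-set quadratic program — the simplex
#' constraint is enforced inside the solve, not by post-hoc rescaling of an
#' unconstrained fit (set `post_normalize = TRUE` for the rescaled-NNLS
#' compatibility behaviour). Deterministic for fixed inputs.
#'
#' @param S Signature-genes x cell-types matrix (the active types).
#' @param t Spot expression vector over the same genes.
#' @param w Optional positive per-gene weights (default all 1).
#' @param post_normalize If TRUE, solve the nonnegative LS without the sum
#'   constraint and rescale the solution to sum 1.
#' @return Named fraction vector on the simplex. Attribute `flag` is one of
#'   `"ok"`, `"zero_target"` (all-zero t: uniform fractions returned) or
#'   `"rank_deficient"`.
#' @export
solve_constrained_wls <- function(S, t, w = NULL, post_normalize = FALSE) {
  S <- as.matrix(S)
  K <- ncol(S)
  if (K < 1L) stop_input("signature must have at least one cell type")
  if (length(t) != nrow(S)) stop_input("length(t) != nrow(S)")
  if (is.null(w)) w <- rep(1, nrow(S))
  if (length(w) != nrow(S) || any(w <= 0) || anyNA(w))
    stop_input("weights must be positive, one per signature gene")
  types <- colnames(S)
  if (all(t == 0)) {
    f <- rep(1 / K, K)
    return(structure(stats::setNames(f, types), flag = "zero_target"))
  }
  Sw <- S * sqrt(w)
  tw <- t * sqrt(w)
  if (post_normalize) {
    # nonnegative LS only, then rescale onto the simplex
    D <- crossprod(Sw); dd <- as.numeric(crossprod(Sw, tw))
    f <- nnls_active(D, dd)
    s <- sum(f)
    f <- if (s > 0) f / s else rep(1 / K, K)
    return(structure(stats::setNames(f, types), flag = "ok"))
  }
  res <- simplex_qp(crossprod(Sw), as.numeric(crossprod(Sw, tw)))
  structure(stats::setNames(res$f, types),
            flag = if (res$rank_deficient) "rank_deficient" else "ok")
}

# Plain NNLS (no sum constraint) by the same active-set machinery on the
# normal equations; used only by the post_normalize compatibility mode and
# the unweighted benchmark baseline.
nnls_active <- function(D, d) {
  K <- length(d)
  passive <- rep(FALSE, K)
  x <- numeric(K)
  for (iter in seq_len(30L * K + 30L)) {
    g <- d - as.numeric(D %*% x)
    cand <- which(!passive & g > 1e-12)
    if (!length(cand)) break
    passive[cand[which.max(g[cand])]] <- TRUE
    repeat {
      z <- numeric(K)
      zz <- tryCatch(solve(D[passive, passive, drop = FALSE], d[passive]),
                     error = function(e)
                       as.numeric(MASS::ginv(D[passive, passive, drop = FALSE]) %*% d[passive]))
      z[passive] <- zz
      if (all(z[passive] > 1e-12)) { x <- z; break }
      idx <- which(passive & z <= 1e-12)
      alpha <- min(x[idx] / (x[idx] - z[idx] + 1e-300))
      x <- x + alpha * (z - x)
      passive[x <= 1e-12 & passive] <- FALSE
      x[!passive] <- 0
    }
  }
  x
}

#' Dampened inverse-fitted-value weights
#'
#' Raw DWLS weights are `1 / (S f)_g^2` — each gene's squared fitted value —
#' so the fit minimizes relative rather than absolute error. To stop
#' low-expression genes from dominating, weights are capped at `d` times the
#' smallest weight: `w_g = min(1 / max((S f)_g^2, eps), d * min_g' w_g')`.
#' `d = 1` collapses to equal weights (unweighted up to scale); `d = Inf`
#' leaves weights uncapped.
#'
#' @param S Signature matrix.
#' @param f Fraction vector on the simplex.
#' @param d Damping constant (>= 1 to have any effect).
#' @param eps Floor on squared fitted values guarding division by zero.
#' @return Positive per-gene weight vector.
#' @export
dampened_weights <- function(S, f, d, eps = 1e-12) {
  fitted <- as.numeric(as.matrix(S) %*% f)
  w <- 1 / pmax(fitted^2, eps)
  pmin(w, d * min(w))
}

# Iterated dampened solve at a fixed damping constant: OLS initialization,
# then reweight / re-solve until the fractions stop moving.
dwls_iterate <- function(S, t, d, cfg) {
  f <- solve_constrained_wls(S, t)
  converged <- FALSE
  iterations <- 0L
  w <- rep(1, nrow(S))
  for (i in seq_len(cfg$max_iter)) {
    w <- dampened_weights(S, f, d)
    f_new <- solve_constrained_wls(S, t, w)
    iterations <- i
    if (max(abs(f_new - f)) < cfg$tol) { f <- f_new; converged <- TRUE; break }
    f <- f_new
  }
  list(f = f, weights = w, iterations = iterations, converged = converged)
}

#' Cross-validate the damping constant
#'
#' For every candidate d, the iterated dampened solve is repeated on
#' `cv_folds` random half-gene subsamples (the same subsamples for every
#' candidate, drawn from `cfg$seed`) and the mean across-subsample variance
#' of the estimated fractions is recorded. The candidate with the smallest
#' variance wins; ties go to the smallest d.
#'
#' @param S Signature matrix (needs at least `2 * cv_folds` genes).
#' @param t Spot expression vector.
#' @param cfg A [solver_config()].
#' @return The chosen damping constant, with the per-candidate variances in
#'   attribute `cv_variance`.
#' @export
select_damping <- function(S, t, cfg = solver_config()) {
  S <- as.matrix(S)
  n_genes <- nrow(S)
  if (n_genes < 2L * cfg$cv_folds)
    stop_input("need >= %d signature genes for %d-fold damping selection, got %d",
               2L * cfg$cv_folds, cfg$cv_folds, n_genes)
  if (ncol(S) == 1L)          # simplex of dimension 0: any d is equivalent
    return(structure(cfg$damping_candidates[1L],
                     cv_variance = stats::setNames(0, cfg$damping_candidates[1L])))
  subsets <- with_seed(cfg$seed, lapply(seq_len(cfg$cv_folds), function(i)
    sample.int(n_genes, floor(n_genes / 2))))
  scores <- vapply(cfg$damping_candidates, function(d) {
    fs <- vapply(subsets, function(idx)
      dwls_iterate(S[idx, , drop = FALSE], t[idx], d, cfg)$f,
      numeric(ncol(S)))
    mean(apply(matrix(fs, nrow = ncol(S)), 1L, stats::var))
  }, numeric(1L))
  best <- which(scores <= min(scores) + 1e-12)[1L]
  structure(cfg$damping_candidates[best],
            cv_variance = stats::setNames(scores, cfg$damping_candidates))
}

#' Deconvolve a single spot
#'
#' With `fixed_weights` supplied this is one weighted constrained solve
#' (cluster-shared weights). Otherwise the damping constant is
#' cross-validated (unless `d` is given) and the dampened iteration runs to
#' convergence: unweighted fit, reweight by dampened inverse squared fitted
#' values, re-solve.
#'
#' @param S Signature matrix restricted to the spot's active types.
#' @param t Spot expression vector over the signature genes.
#' @param cfg A [solver_config()].
#' @param fixed_weights Optional per-gene weights; skips the iteration.
#' @param d Optional damping constant; skips cross-validation.
#' @return Named fraction vector; attributes `d`, `iterations`, `converged`.
#' @export
deconvolve_spot <- function(S, t, cfg = solver_config(), fixed_weights = NULL,
                            d = NULL) {
  S <- as.matrix(S)
  if (!is.null(fixed_weights)) {
    f <- solve_constrained_wls(S, t, fixed_weights)
    return(structure(f, d = NA_real_, iterations = 1L, converged = TRUE,
                     flag = attr(f, "flag")))
  }
  if (is.null(d)) d <- as.numeric(select_damping(S, t, cfg))
  it <- dwls_iterate(S, t, d, cfg)
  if (!it$converged)
    warning(sprintf("dampened iteration stopped at max_iter = %d without converging",
                    cfg$max_iter))
  structure(it$f, d = d, iterations = it$iterations, converged = it$converged)
}

#' Deconvolve all spots with enrichment masking and cluster-shared weights
#'
#' The full composition estimator. Per spot cluster: (i) the active cell
#' types are the union of enrichment-selected types over the cluster's
#' spots; (ii) the damping constant and the gene weight vector are fitted
#' once on the cluster's mean expression profile, so all spots in a cluster
#' share them; (iii) each spot is solved with those weights over its own
#' enrichment-selected types; (iv) types estimated below
#' `cfg$min_frequency` are removed and the weighted solve re-run on the
#' survivors. Types never selected for a spot have fraction exactly 0.
#'
#' @param spot_expr Genes x spots matrix (same normalization as the
#'   signature).
#' @param sig Signature-genes x cell-types matrix.
#' @param enr An `enrichment_matrix` from [page_enrichment()] /
#'   [binarize_enrichment()]; its types must match the signature columns.
#' @param clusters Optional data.frame (`sample_id`, `label`) of spot
#'   clusters; `NULL` treats all spots as one cluster (see
#'   [cluster_spots_kmeans()] for a built-in clustering fallback).
#' @param cfg A [solver_config()].
#' @return A `spot_composition`: list with `fractions` (spots x types matrix
#'   on the simplex), per-spot `flags` (cluster, enrichment fallback, second
#'   round run, convergence), and per-cluster damping constants `d`.
#' @export
deconvolve <- function(spot_expr, sig, enr, clusters = NULL,
                       cfg = solver_config()) {
  assert_expression_matrix(spot_expr, "spot expression matrix")
  if (!inherits(enr, "enrichment_matrix"))
    stop_input("'enr' must be an enrichment_matrix (see page_enrichment)")
  types <- colnames(sig)
  if (is.null(types) || !setequal(types, rownames(enr$mask)))
    stop_input("signature cell types and enrichment rows do not match")
  spots <- colnames(spot_expr)
  missing_spots <- setdiff(spots, colnames(enr$mask))
  if (length(missing_spots))
    stop_input("enrichment mask missing %d spot(s)", length(missing_spots))
  genes <- intersect(rownames(sig), rownames(spot_expr))
  if (length(genes) < 2L)
    stop_input("fewer than 2 signature genes found in the spot matrix")
  if (length(genes) < nrow(sig))
    warning(sprintf("%d signature gene(s) absent from the spot matrix",
                    nrow(sig) - length(genes)))
  S <- as.matrix(sig)[genes, , drop = FALSE]
  Tm <- spot_expr[genes, , drop = FALSE]
  mask <- enr$mask[types, spots, drop = FALSE]

  if (is.null(clusters)) {
    clusters <- data.frame(sample_id = spots, label = "all",
                           stringsAsFactors = FALSE)
  }
  assert_labels(clusters, spots)
  cl <- clusters$label[match(spots, clusters$sample_id)]

  K <- length(types)
  fractions <- matrix(0, nrow = length(spots), ncol = K,
                      dimnames = list(spots, types))
  flags <- data.frame(spot_id = spots, cluster = cl,
                      enrichment_fallback = as.logical(enr$fallback[spots]),
                      second_round = FALSE, converged = TRUE,
                      stringsAsFactors = FALSE, row.names = spots)
  d_by_cluster <- stats::setNames(numeric(0), character(0))

  for (cluster in unique(cl)) {
    in_cl <- spots[cl == cluster]
    active <- types[rowSums(mask[, in_cl, drop = FALSE]) > 0]
    S_cl <- S[, active, drop = FALSE]
    t_bar <- rowMeans(Tm[, in_cl, drop = FALSE])
    fit_cl <- deconvolve_spot(S_cl, t_bar, cfg)
    d_cl <- attr(fit_cl, "d")
    w_cl <- dampened_weights(S_cl, as.numeric(fit_cl), d_cl)
    d_by_cluster[cluster] <- d_cl

    for (s in in_cl) {
      act_s <- active[mask[active, s] > 0]
      f1 <- solve_constrained_wls(S[, act_s, drop = FALSE], Tm[, s], w_cl)
      keep <- act_s[f1 >= cfg$min_frequency]
      if (!length(keep)) keep <- act_s[which.max(f1)]
      if (length(keep) < length(act_s)) {
        f2 <- solve_constrained_wls(S[, keep, drop = FALSE], Tm[, s], w_cl)
        flags[s, "second_round"] <- TRUE
        fractions[s, keep] <- f2
      } else {
        fractions[s, act_s] <- f1
      }
    }
  }
  structure(list(fractions = fractions, flags = flags, d = d_by_cluster,
                 config = cfg),
            class = "spot_composition")
}

#' @export
print.spot_composition <- function(x, ...) {
  cat(sprintf("spot_composition: %d spots x %d cell types\n",
              nrow(x$fractions), ncol(x$fractions)))
  cat(sprintf("  clusters: %d (damping constants %s)\n", length(x$d),
              paste(format(x$d), collapse = ", ")))
  cat(sprintf("  second round run for %d spot(s); %d enrichment fallback(s)\n",
              sum(x$flags$second_round), sum(x$flags$enrichment_fallback)))
  invisible(x)
}

#' @export
as.matrix.spot_composition <- function(x, ...) x$fractions

#' Unweighted, unfiltered baseline deconvolution
#'
#' Solves every spot over every cell type with unit weights and no
#' enrichment masking or low-frequency filtering — the reference point
#' against which enrichment-guided dampened fitting is compared in the
#' benchmark.
#'
#' @param spot_expr Genes x spots matrix.
#' @param sig Signature matrix.
#' @param post_normalize Use rescaled NNLS instead of the simplex-constrained
#'   solve.
#' @return Spots x types fraction matrix.
#' @export
deconvolve_baseline <- function(spot_expr, sig, post_normalize = FALSE) {
  genes <- intersect(rownames(sig), rownames(spot_expr))
  S <- as.matrix(sig)[genes, , drop = FALSE]
  out <- t(apply(spot_expr[genes, , drop = FALSE], 2L, function(t)
    solve_constrained_wls(S, t, post_normalize = post_normalize)))
  dimnames(out) <- list(colnames(spot_expr), colnames(sig))
  out
}

#' Seeded k-means clustering of spots on top principal components
#'
#' A lightweight stand-in for graph-based spot clustering when no cluster
#' labels are supplied: spots are embedded with PCA on log1p expression and
#' grouped by k-means.
#'
#' @param spot_expr Genes x spots matrix.
#' @param k Number of clusters.
#' @param n_pcs Principal components used (default 10, capped by the data).
#' @param seed Integer seed.
#' @return Data.frame (`sample_id`, `label`) usable as the `clusters`
#'   argument of [deconvolve()].
#' @export
cluster_spots_kmeans <- function(spot_expr, k, n_pcs = 10L, seed = 1L) {
  assert_expression_matrix(spot_expr, "spot expression matrix")
  if (k < 1L || k > ncol(spot_expr))
    stop_input("'k' must be between 1 and the number of spots")
  x <- t(log1p(spot_expr))
  keep <- apply(x, 2L, stats::sd) > 0
  x <- x[, keep, drop = FALSE]
  n_pcs <- min(n_pcs, ncol(x), nrow(x) - 1L)
  pcs <- stats::prcomp(x, center = TRUE, scale. = FALSE,
                       rank. = n_pcs)$x
  km <- with_seed(seed, stats::kmeans(pcs, centers = k, nstart = 10L,
                                      iter.max = 50L))
  data.frame(sample_id = colnames(spot_expr),
             label = paste0("cluster_", km$cluster),
             stringsAsFactors = FALSE)
}
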