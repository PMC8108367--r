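test_that("noiseless mixtures are recovered exactly on the simplex", {
  withr::with_seed(1, {
    for (i in 1:10) {
      S <- rsignature(40, 4)
      f <- rsimplex(4)
      fh <- solve_constrained_wls(S, as.numeric(S %*% f))
      expect_lt(max(abs(fh - f)), 1e-6)
      expect_equal(sum(fh), 1, tolerance = 1e-9)
    }
  })
})

test_that("degenerate solves honour their contracts", {
  S1 <- rsignature(10, 1, seed = 2)
  expect_identical(as.numeric(solve_constrained_wls(S1, rexp(10))), 1)

  S <- rsignature(10, 3, seed = 3)
  fz <- solve_constrained_wls(S, rep(0, 10))
  expect_equal(as.numeric(fz), rep(1 / 3, 3))
  expect_identical(attr(fz, "flag"), "zero_target")

  # duplicated column: rank deficient but still solved on the simplex
  Sdup <- cbind(S[, c(1, 1, 2)])
  colnames(Sdup) <- c("a", "a2", "b")
  f <- withr::with_seed(4, solve_constrained_wls(Sdup, as.numeric(S[, 1:2] %*% c(0.4, 0.6))))
  expect_equal(sum(f), 1, tolerance = 1e-8)
  expect_equal(unname(f[["b"]]), 0.6, tolerance = 1e-4)
})

test_that("the constrained solve beats random feasible points and an independent QP", {
  withr::with_seed(7, {
    for (i in 1:8) {
      K <- sample(2:4, 1)
      S <- rsignature(40, K)
      t <- rexp(40); w <- rexp(40) + 0.05
      fh <- solve_constrained_wls(S, t, w)
      rand <- replicate(3000, rsimplex(K))
      best_rand <- min(apply(rand, 2, wls_objective, S = S, t = t, w = w))
      expect_lte(wls_objective(S, t, fh, w), best_rand + 1e-10)

      Sw <- S * sqrt(w)
      qp <- pracma::quadprog(2 * crossprod(Sw), -2 * as.numeric(crossprod(Sw, t * sqrt(w))),
                             Aeq = matrix(1, 1, K), beq = 1, lb = rep(0, K))
      expect_equal(wls_objective(S, t, fh, w),
                   qp$fval + sum(w * t^2), tolerance = 1e-8)
    }
  })
})

test_that("solutions are equivariant under gene and type permutations", {
  S <- rsignature(30, 4, seed = 11)
  t <- withr::with_seed(12, rexp(30))
  w <- withr::with_seed(13, rexp(30) + 0.1)
  f <- solve_constrained_wls(S, t, w)
  pg <- withr::with_seed(14, sample(30))
  pt <- c(3, 1, 4, 2)
  f_g <- solve_constrained_wls(S[pg, ], t[pg], w[pg])
  f_t <- solve_constrained_wls(S[, pt], t, w)
  expect_equal(f, f_g, tolerance = 1e-8)
  expect_equal(as.numeric(f[pt]), as.numeric(f_t), tolerance = 1e-8)
})

test_that("dampened weights invert squared fitted values and cap at d times the minimum", {
  S <- rsignature(25, 3, seed = 21)
  f <- rsimplex(3)
  w <- dampened_weights(S, f, d = 4)
  fitted <- as.numeric(S %*% f)
  manual <- pmin(1 / pmax(fitted^2, 1e-12),
                 4 * min(1 / pmax(fitted^2, 1e-12)))   # loop-free oracle
  expect_equal(w, manual, tolerance = 1e-12)

  # constant fitted values: all weights equal, any d >= 1 is a no-op
  Sc <- matrix(1, 10, 2, dimnames = list(paste0("g", 1:10), c("a", "b")))
  expect_equal(dampened_weights(Sc, c(0.5, 0.5), 1), rep(1, 10))
  expect_equal(dampened_weights(Sc, c(0.5, 0.5), 100), rep(1, 10))

  # d = 1 collapses everything to the minimum weight
  w1 <- dampened_weights(S, f, 1)
  expect_equal(w1, rep(min(1 / fitted^2), 25), tolerance = 1e-12)
})

test_that("damping selection tie-breaks to the smallest candidate on noiseless data", {
  S <- rsignature(60, 3, seed = 31)
  t <- as.numeric(S %*% c(0.2, 0.3, 0.5))
  cfg <- solver_config(seed = 5L)
  d <- select_damping(S, t, cfg)
  expect_equal(as.numeric(d), 1)       # 2^0, the smallest candidate

  single <- solver_config(damping_candidates = 64, seed = 5L)
  expect_equal(as.numeric(select_damping(S, t, single)), 64)

  expect_error(select_damping(S[1:10, ], t[1:10], cfg), "signature genes")
})

test_that("damping selection avoids the uncapped extreme under heteroscedastic noise", {
  # high-expression genes noisier: sd proportional to fitted value, so the
  # raw 1/(Sf)^2 weights over-trust low-expression genes and finite damping
  # should win in most runs
  finite_wins <- 0L
  runs <- 25L
  cfg <- solver_config(cv_folds = 6L, seed = 0L)
  for (r in seq_len(runs)) {
    S <- rsignature(50, 3, seed = 100 + r)
    f <- withr::with_seed(200 + r, rsimplex(3))
    mu <- as.numeric(S %*% f)
    t <- withr::with_seed(300 + r, pmax(mu + stats::rnorm(50, sd = 0.6 * mu), 0))
    cfg_r <- solver_config(cv_folds = 6L, seed = r)
    d <- as.numeric(select_damping(S, t, cfg_r))
    if (d < max(cfg$damping_candidates)) finite_wins <- finite_wins + 1L
  }
  expect_gte(finite_wins / runs, 0.8)
})

test_that("the dampened iteration converges fast on noiseless data and reduces to plain LS with unit weights", {
  S <- rsignature(45, 4, seed = 41)
  f_star <- withr::with_seed(42, rsimplex(4))
  t <- as.numeric(S %*% f_star)
  cfg <- solver_config(seed = 2L)
  f <- deconvolve_spot(S, t, cfg, d = 8)
  expect_lte(attr(f, "iterations"), 3L)
  expect_lt(max(abs(f - f_star)), 1e-6)

  noisy <- withr::with_seed(43, t + rexp(45) * 0.1)
  fw <- deconvolve_spot(S, noisy, cfg, fixed_weights = rep(1, 45))
  expect_equal(as.numeric(fw), as.numeric(solve_constrained_wls(S, noisy)),
               tolerance = 1e-10)
})

test_that("each reweighted solve weakly improves its own weighted objective", {
  S <- rsignature(35, 4, seed = 51)
  t <- withr::with_seed(52, as.numeric(S %*% rsimplex(4)) * rexp(35))
  cfg <- solver_config(seed = 1L)
  f <- solve_constrained_wls(S, t)
  for (i in 1:12) {
    w <- dampened_weights(S, f, d = 16)
    f_new <- solve_constrained_wls(S, t, w)
    expect_lte(wls_objective(S, t, f_new, w), wls_objective(S, t, f, w) + 1e-9)
    f <- f_new
  }
})

test_that("single-spot deconvolution recovers Poisson-noised mixtures", {
  # depth 2000, 3 types, 60 markers per type, 50 replicates, seed 7
  sc <- synthetic_scenario(n_types = 3L, n_genes = 180L, markers_per_type = 60L,
                           marker_effect = 10, depth = 2000, seed = 7L)
  ref <- synthesize_reference(sc)
  S <- ref$profiles
  cfg <- solver_config(seed = 7L)
  errs <- withr::with_seed(7, {
    vapply(1:50, function(r) {
      f_star <- rsimplex(3)
      lambda <- as.numeric(S %*% f_star)
      t <- rpois(nrow(S), lambda / sum(lambda) * 2000)
      f <- deconvolve_spot(S, t, cfg, d = 4)
      mean(abs(f - f_star))
    }, numeric(1))
  })
  expect_lt(mean(errs), 0.05)
})

test_that("full deconvolution respects masks, clusters, and the min-frequency second round", {
  ref <- toy_reference(n_types = 3L, n_genes = 60L, mpt = 12L, seed = 61L,
                       effect = 12)
  norm <- normalize_library_size(ref$expr)
  rk <- rank_markers_gini(norm, ref$labels)
  sig <- build_signature(norm, ref$labels, rk, top_n = 12L)
  sets <- marker_sets_from_signature(sig, rk, top_n = 12L)

  truth <- random_compositions(12, colnames(sig), cells_per_spot = 5L,
                               max_types = 2L, seed = 3L)
  spots <- synthesize_spots(ref$profiles, truth, depth = 4000, seed = 4L)
  spots_norm <- normalize_library_size(spots$expr)
  enr <- page_enrichment(spots_norm, sets)
  cfg <- solver_config(cv_folds = 5L, seed = 9L)
  fit <- deconvolve(spots_norm, sig, enr, clusters = NULL, cfg = cfg)

  expect_equal(unname(rowSums(fit$fractions)), rep(1, 12), tolerance = 1e-6)
  expect_true(all(fit$fractions >= 0 & fit$fractions <= 1))
  # enrichment-masked types are exactly zero
  for (s in rownames(fit$fractions)) {
    off <- colnames(sig)[enr$mask[colnames(sig), s] == 0]
    expect_identical(unname(fit$fractions[s, off]),
                     rep(0, length(off)))
  }
  # the second round only ever runs when a low-frequency type was removed
  expect_true(all(!fit$flags$second_round |
                    rowSums(fit$fractions == 0) > 0))
})

test_that("low-frequency removal is strict and zeros are exact", {
  S <- rsignature(60, 3, seed = 91)
  f_star <- c(0.965, 0.03, 0.005)          # one type above, one below 0.02
  t <- as.numeric(S %*% f_star)
  spot_expr <- matrix(t, ncol = 1, dimnames = list(rownames(S), "sp1"))
  spot_expr <- cbind(spot_expr, sp2 = t)
  es <- matrix(5, 3, 2, dimnames = list(colnames(S), colnames(spot_expr)))
  fit <- deconvolve(spot_expr, S, binarize_enrichment(es, 2),
                    cfg = solver_config(cv_folds = 5L, seed = 1L))
  expect_identical(unname(fit$fractions[, 3]), c(0, 0))    # < 0.02: removed
  expect_gt(fit$fractions[1, 2], 0)                        # > 0.02: kept
  expect_true(all(fit$flags$second_round))
})

test_that("identical spots in one cluster produce identical rows", {
  S <- rsignature(50, 3, seed = 71)
  t <- as.numeric(S %*% c(0.5, 0.3, 0.2))
  spot_expr <- matrix(rep(t, 4), ncol = 4,
                      dimnames = list(rownames(S), paste0("sp", 1:4)))
  es <- matrix(3, 3, 4, dimnames = list(colnames(S), colnames(spot_expr)))
  enr <- binarize_enrichment(es, 2)
  fit <- deconvolve(spot_expr, S, enr, cfg = solver_config(cv_folds = 5L, seed = 1L))
  for (i in 2:4)
    expect_identical(fit$fractions[1, ], fit$fractions[i, ])
  expect_equal(unname(fit$fractions[1, ]), c(0.5, 0.3, 0.2), tolerance = 1e-5)
})

test_that("k-means fallback clustering is deterministic under a fixed seed", {
  ref <- toy_reference(seed = 81L)
  cl1 <- cluster_spots_kmeans(ref$expr, k = 3L, seed = 42L)
  cl2 <- cluster_spots_kmeans(ref$expr, k = 3L, seed = 42L)
  expect_identical(cl1, cl2)
  expect_setequal(cl1$sample_id, colnames(ref$expr))
})
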