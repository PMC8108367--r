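test_that("the grid rule connects rook neighbours and excludes diagonals", {
  coords <- data.frame(sample_id = paste0("s", 1:4),
                       x = c(0, 1, 0, 1), y = c(0, 0, 1, 1))
  net <- build_neighbor_network(coords, rule = "grid")
  expect_equal(nrow(net$edges), 4L)          # sides of the unit square only
  pairs <- apply(net$edges, 1, function(e) paste(sort(e), collapse = "-"))
  expect_setequal(pairs, c("s1-s2", "s1-s3", "s2-s4", "s3-s4"))
})

test_that("radius and degenerate inputs follow their contracts", {
  coords <- data.frame(sample_id = paste0("s", 1:3),
                       x = c(0, 1, 2), y = c(0, 0, 0))
  empty <- build_neighbor_network(coords, rule = "radius", param = 0.5)
  expect_equal(nrow(empty$edges), 0L)
  expect_error(build_neighbor_network(coords, rule = "radius"), "cutoff")

  same <- data.frame(sample_id = c("a", "b"), x = c(1, 1), y = c(2, 2))
  expect_error(build_neighbor_network(same), "coincide")
  expect_error(build_neighbor_network(coords[1, ]), "2 spots")
})

test_that("delaunay edges match an independent triangulation", {
  coords <- withr::with_seed(15, data.frame(sample_id = sprintf("p%02d", 1:20),
                                            x = runif(20), y = runif(20)))
  net <- build_neighbor_network(coords, rule = "delaunay")
  pts <- paste(sprintf("%.17g", coords$x), sprintf("%.17g", coords$y),
               collapse = " ")
  script <- paste(
    "import sys; import numpy as np",
    "from scipy.spatial import Delaunay",
    "v = np.array(sys.argv[1].split(), float).reshape(-1, 2)",
    "tri = Delaunay(v)",
    "e = set()",
    "for s in tri.simplices:",
    "    for a in range(3):",
    "        for b in range(a + 1, 3):",
    "            e.add(tuple(sorted((int(s[a]), int(s[b])))))",
    "print('\\n'.join(f'{a} {b}' for a, b in sorted(e)))",
    sep = "\n")
  out <- suppressWarnings(
    tryCatch(system2("python", c("-c", shQuote(script), shQuote(pts)),
                     stdout = TRUE),
             error = function(e) NULL))
  skip_if(is.null(out) || !length(out), "python/scipy oracle unavailable")
  oracle <- t(vapply(strsplit(out, " "), function(p)
    sort(coords$sample_id[as.integer(p) + 1L]), character(2)))
  mine <- t(apply(net$edges, 1, sort))
  expect_setequal(paste(mine[, 1], mine[, 2]), paste(oracle[, 1], oracle[, 2]))
})

test_that("within-type-only adjacency gives Q = 1 and a forced cross edge gives Q = -1", {
  comp <- onehot_composition(c("a", "a", "b", "b"))
  net <- manual_network(4, rbind(c(1, 2), c(3, 4)))
  res <- assortativity(comp, net)
  expect_equal(res$Q, 1)
  expect_equal(sum(res$a_k), 1, tolerance = 1e-12)

  comp2 <- onehot_composition(c("a", "b"))
  net2 <- manual_network(2, rbind(c(1, 2)))
  res2 <- assortativity(comp2, net2)
  expect_equal(unname(res2$q_kk), c(0, 0))
  expect_equal(res2$Q, -1)

  uniform <- onehot_composition(c("a", "a"))
  expect_error(assortativity(uniform, manual_network(2, rbind(c(1, 2)))),
               "single cell type")
})

test_that("fractional Q matches the ordered-pair loop oracle and is label-invariant", {
  withr::with_seed(33, {
    for (i in 1:10) {
      n <- sample(4:10, 1)
      W <- matrix(rexp(n * 3), n, 3); W <- W / rowSums(W)
      dimnames(W) <- list(sprintf("sp%02d", 1:n), c("x", "y", "z"))
      # random connected-ish graph: a path plus random extras
      edges <- cbind(1:(n - 1), 2:n)
      extra <- matrix(sample(n, 4, replace = TRUE), 2)
      extra <- extra[, extra[1, ] != extra[2, ], drop = FALSE]
      edges <- unique(rbind(edges, t(extra)))
      edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
      # dedupe unordered pairs
      key <- apply(edges, 1, function(e) paste(sort(e), collapse = "-"))
      edges <- edges[!duplicated(key), , drop = FALSE]
      net <- manual_network(n, edges, ids = rownames(W))
      adj <- matrix(0, n, n)
      adj[edges] <- 1; adj[edges[, c(2, 1), drop = FALSE]] <- 1
      expect_equal(assortativity(W, net)$Q, assortativity_loop_oracle(W, adj),
                   tolerance = 1e-12)

      # permuting spot ids and type columns leaves Q unchanged
      perm <- sample(n)
      W2 <- W[perm, c(3, 1, 2)]
      net2 <- manual_network(n, edges, ids = rownames(W))
      expect_equal(assortativity(W2, net2)$Q, assortativity(W, net)$Q,
                   tolerance = 1e-12)
    }
  })
})

test_that("binary compositions on regular graphs reduce to Newman's coefficient", {
  skip_if_not_installed("igraph")
  # cycles and complete graphs are regular: node and edge-end frequencies
  # coincide, so the fractional statistic must equal Newman's exactly
  cases <- list(
    list(edges = rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1)),
         labels = c("a", "a", "b", "b")),
    list(edges = rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(5, 1)),
         labels = c("a", "b", "a", "b", "b")),
    list(edges = t(combn(4, 2)), labels = c("a", "b", "b", "b")))
  for (cs in cases) {
    n <- max(cs$edges)
    W <- onehot_composition(cs$labels)
    net <- manual_network(n, cs$edges, ids = rownames(W))
    g <- igraph::graph_from_edgelist(cs$edges, directed = FALSE)
    ref <- igraph::assortativity_nominal(g, types = as.integer(factor(cs$labels)))
    expect_equal(assortativity(W, net)$Q, ref, tolerance = 1e-12)
  }
})

test_that("joining two identical spots does not decrease Q when other edges cross types", {
  W <- onehot_composition(c("a", "a", "b", "b"))
  cross_only <- manual_network(4, rbind(c(2, 3)))
  with_tie <- manual_network(4, rbind(c(2, 3), c(1, 2)))
  expect_gt(assortativity(W, with_tie)$Q, assortativity(W, cross_only)$Q)
})

test_that("assortativity trends aggregate per group", {
  W1 <- onehot_composition(c("a", "a", "b", "b"))
  net1 <- manual_network(4, rbind(c(1, 2), c(3, 4)))
  W2 <- onehot_composition(c("a", "b", "a", "b"))
  net2 <- manual_network(4, rbind(c(1, 2), c(3, 4)))
  tr <- assortativity_trend(list(W1, W1, W2), list(net1, net1, net2),
                            c("early", "early", "late"))
  expect_equal(unname(tr$group_means["early"]), 1)
  expect_equal(unname(tr$group_means["late"]), assortativity(W2, net2)$Q)
  expect_error(assortativity_trend(list(), list(), character(0)), "no samples")
})
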