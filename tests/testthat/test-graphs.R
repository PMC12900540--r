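test_that("knn adjacency handles minimal, complete and tied cases", {
  expect_equal(build_knn_adjacency(cbind(c(0, 1), c(0, 0)), 1),
               matrix(c(0, 1, 1, 0), 2, 2))

  set.seed(3)
  coords <- cbind(runif(5), runif(5))
  a <- build_knn_adjacency(coords, 4)
  expect_equal(a, 1 - diag(5))

  # collinear points: middle spot's distance tie resolves to the lower index
  a3 <- build_knn_adjacency(cbind(c(0, 1, 2), c(0, 0, 0)), 1)
  expect_equal(a3, matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3, 3))

  expect_error(build_knn_adjacency(coords, 5), "k must satisfy")
})

test_that("knn adjacency is invariant under rigid motions of the coordinates", {
  set.seed(11)
  coords <- cbind(runif(20), runif(20))
  a <- build_knn_adjacency(coords, 3)
  th <- 0.77
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  moved <- coords %*% rot + matrix(c(5, -2), 20, 2, byrow = TRUE)
  expect_equal(build_knn_adjacency(moved, 3), a)
})

test_that("expected co-occurrence matches hand and enumeration oracles", {
  edge <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(cooccurrence(edge, walk_config(1)), edge)

  # two disconnected 2-node components: no cross-component mass at any T
  block <- rbind(cbind(edge, matrix(0, 2, 2)), cbind(matrix(0, 2, 2), edge))
  f <- cooccurrence(block, walk_config(3))
  expect_true(all(f[1:2, 3:4] == 0) && all(f[3:4, 1:2] == 0))

  set.seed(5)
  coords <- cbind(runif(5), runif(5))
  a <- build_knn_adjacency(coords, 2)
  for (T in 1:3)
    expect_equal(cooccurrence(a, walk_config(T)), enum_cooccurrence(a, T),
                 tolerance = 1e-12)

  expect_error(cooccurrence(diag(0, 3), walk_config(1)), "isolated")
})

test_that("sampled walks converge to the expected co-occurrence", {
  path4 <- matrix(0, 4, 4)
  path4[cbind(1:3, 2:4)] <- 1
  path4 <- path4 + t(path4)
  fe <- cooccurrence(path4, walk_config(3))
  fs <- cooccurrence(path4, walk_config(3, mode = "sampled",
                                        walks_per_node = 1e4, seed = 1))
  expect_lt(max(abs(fe - fs)), 0.02)
})

test_that("ppmi reproduces the two-node value and its clipping conventions", {
  p <- compute_ppmi(matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(p, matrix(c(0, log(2), log(2), 0), 2, 2))

  # independence (all frequencies equal) gives identically zero
  expect_equal(compute_ppmi(matrix(1, 3, 3)), matrix(0, 3, 3))

  # zero co-occurrence cells stay zero, never -Inf
  f <- matrix(c(0, 2, 0, 2, 0, 1, 0, 1, 0), 3, 3)
  expect_true(all(is.finite(compute_ppmi(f))))
  expect_equal(compute_ppmi(f)[1, 3], 0)

  expect_error(compute_ppmi(matrix(0, 2, 2)), "zero grand total")
})

test_that("ppmi is scale-invariant and zero under factorizing walk laws", {
  set.seed(9)
  f <- matrix(runif(16), 4, 4)
  expect_equal(compute_ppmi(f), compute_ppmi(137.5 * f), tolerance = 1e-12)

  # uniform complete graph: the truncated-walk law approaches independence at
  # rate O(1/T) (the finite-horizon average keeps an O(1/T) memory of the
  # walk's start), so the PPMI vanishes like 1/(4T)
  k4 <- 1 - diag(4)
  dev50 <- max(abs(compute_ppmi(cooccurrence(k4, walk_config(50)))))
  dev500 <- max(abs(compute_ppmi(cooccurrence(k4, walk_config(500)))))
  expect_lt(dev50, 1 / (4 * 50) * 1.1)
  expect_lt(dev500, 1 / (4 * 500) * 1.1)
})

test_that("symmetric normalization has its closed-form values", {
  expect_equal(normalize_adjacency(matrix(0, 3, 3)), diag(3))
  expect_equal(normalize_adjacency(matrix(c(0, 1, 1, 0), 2, 2)),
               matrix(0.5, 2, 2))
  # rows of a d-regular graph's propagation matrix sum to 1 (4-cycle)
  cyc <- matrix(0, 4, 4)
  cyc[cbind(1:4, c(2, 3, 4, 1))] <- 1
  cyc <- cyc + t(cyc)
  expect_equal(unname(rowSums(normalize_adjacency(cyc))), rep(1, 4))
})

test_that("spatial_graph bundles valid graphs and exports sparse files", {
  s <- tiny_slice(n = 15)
  g <- spatial_graph(s, k = 3, walk = walk_config(2))
  expect_true(isSymmetric(g$knn_adjacency))
  expect_true(all(diag(g$knn_adjacency) == 0))
  expect_true(all(g$ppmi >= 0))
  expect_true(all(diag(g$ppmi) == 0))
  # spectral radius of the normalized operators is at most 1
  expect_lte(max(abs(eigen(g$knn_norm, only.values = TRUE)$values)), 1 + 1e-12)
  expect_lte(max(abs(eigen(g$ppmi_norm, only.values = TRUE)$values)), 1 + 1e-12)

  out <- tempfile()
  paths <- export_graph_mtx(g, s$spot_ids, out)
  expect_true(all(file.exists(paths)))
  a_back <- as.matrix(Matrix::readMM(paths[1])) * 1  # pattern mtx reads logical
  expect_equal(unname(a_back), unname(g$knn_adjacency))
})
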