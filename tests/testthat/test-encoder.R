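test_that("linear embedding is the stated affine map", {
  X <- matrix(c(1, 2, 3, 4), 2, 2)
  expect_equal(linear_embed(X, diag(2)), X)
  expect_equal(linear_embed(X * 0, diag(2), b = c(5, 6)),
               matrix(c(5, 5, 6, 6), 2, 2))
  W <- matrix(c(1, -1, 2, 0.5), 2, 2)
  expect_equal(linear_embed(X, W), X %*% W)
  expect_error(linear_embed(X, matrix(0, 3, 2)), "shape mismatch")
})

test_that("gcn layer reduces to known special cases", {
  set.seed(2)
  H <- matrix(rnorm(12), 4, 3)
  W <- matrix(rnorm(9), 3, 3)
  # identity propagation = plain dense layer
  expect_equal(gcn_layer(H, diag(4), W), pmax(H %*% W, 0))
  # row-stochastic averaging with identity weights = neighbourhood average
  P <- matrix(1 / 4, 4, 4)
  expect_equal(gcn_layer(H, P, diag(3), activation = "identity"),
               matrix(colMeans(H), 4, 3, byrow = TRUE))
  expect_equal(gcn_layer(H * 0, diag(4), W), matrix(0, 4, 3))
})

test_that("branch encoding is deterministic and zero-preserving", {
  gm <- tiny_graph_mats()
  set.seed(1)
  cfg <- encoder_config(4, embed_dim = 4, gcn_dims = c(4, 3, 2))
  pars <- stransfer:::init_branch(4, c(4, 3, 2))
  E <- matrix(rnorm(24), 6, 4)
  b1 <- encode_branch(E, gm$A, pars)
  b2 <- encode_branch(E, gm$A, pars)
  expect_identical(b1, b2)
  z <- encode_branch(E * 0, gm$A, pars)
  expect_equal(z$f, matrix(0, 6, 2))
  expect_equal(z$mu, matrix(0, 6, 2))
})

test_that("reparameterization has the stated mean, variance and limits", {
  mu <- matrix(c(1, -2, 0.5, 3), 2, 2)
  lv <- matrix(log(c(4, 1, 0.25, 9)), 2, 2)
  expect_equal(reparameterize(mu, lv, eps = 0), mu)
  expect_equal(reparameterize(mu, matrix(-50, 2, 2)), mu, tolerance = 1e-10)

  set.seed(123)
  n <- 1e5
  draws <- replicate(n, reparameterize(mu[1, 1, drop = FALSE],
                                       lv[1, 1, drop = FALSE])[1])
  se_mean <- 2 / sqrt(n)                 # sd = 2
  expect_lt(abs(mean(draws) - 1), 3 * se_mean)
  se_var <- 4 * sqrt(2 / (n - 1))        # var of sample variance ~ 2 sigma^4/(n-1)
  expect_lt(abs(var(draws) - 4), 3 * se_var)
})

test_that("attention fusion is a two-way softmax with the stated limits", {
  u <- matrix(rnorm(8), 4, 2)
  # identical branches: alpha exactly 1/2, fused equals the branch
  af <- attention_fuse(u, u, w = c(1, -2), b = 0.3)
  expect_equal(af$alpha, rep(0.5, 4))
  expect_equal(af$fused, u)
  # zero score weights: alpha 1/2 regardless of inputs
  af2 <- attention_fuse(u, u + 5, w = c(0, 0))
  expect_equal(af2$alpha, rep(0.5, 4))
  # score difference of log 3 gives alpha = 0.75 on the favoured branch
  uA <- matrix(log(3), 1, 1)
  uP <- matrix(0, 1, 1)
  af3 <- attention_fuse(uA, uP, w = 1)
  expect_equal(af3$alpha, 0.75)
  expect_equal(af3$fused[1, 1], 0.75 * log(3))
  expect_error(attention_fuse(u, u[, 1, drop = FALSE], w = c(1, 1)), "width")
})

test_that("the full encoder is permutation-equivariant", {
  set.seed(21)
  n <- 6
  gm <- tiny_graph_mats(n = n)
  X <- matrix(rnorm(n * 5), n, 5)
  cfg <- encoder_config(5, embed_dim = 4, gcn_dims = c(4, 3, 2))
  pars <- stransfer:::init_encoder(cfg, c("A", "P"))
  h <- stransfer:::encoder_forward(X, gm, pars, eps = 0)$h
  perm <- sample(n)
  gmp <- lapply(gm, function(g) g[perm, perm])
  hp <- stransfer:::encoder_forward(X[perm, ], gmp, pars, eps = 0)$h
  expect_equal(hp, h[perm, ], tolerance = 1e-12)
})

test_that("tied branches with a shared graph collapse to a single branch", {
  set.seed(22)
  gm <- tiny_graph_mats()
  X <- matrix(rnorm(6 * 5), 6, 5)
  cfg <- encoder_config(5, embed_dim = 4, gcn_dims = c(4, 3, 2))
  pars <- stransfer:::init_encoder(cfg, c("A", "P"))
  pars$branches$P <- pars$branches$A
  gmt <- list(A = gm$A, P = gm$A)
  fw <- stransfer:::encoder_forward(X, gmt, pars, eps = 0)
  expect_equal(fw$h, cbind(fw$acts$A$f, fw$acts$A$z), tolerance = 1e-12)
  expect_true(all(fw$alpha_f > 0 & fw$alpha_f < 1))
  expect_true(all(abs(fw$alpha_f - 0.5) < 1e-12))
})

test_that("forward passes are reproducible under a seed and exact at eps = 0", {
  set.seed(23)
  gm <- tiny_graph_mats()
  X <- matrix(rnorm(6 * 5), 6, 5)
  cfg <- encoder_config(5, embed_dim = 4, gcn_dims = c(4, 3, 2))
  pars <- stransfer:::init_encoder(cfg, c("A", "P"))
  set.seed(99); h1 <- stransfer:::encoder_forward(X, gm, pars, eps = NULL)$h
  set.seed(99); h2 <- stransfer:::encoder_forward(X, gm, pars, eps = NULL)$h
  expect_identical(h1, h2)
  expect_identical(stransfer:::encoder_forward(X, gm, pars, eps = 0)$h,
                   stransfer:::encoder_forward(X, gm, pars, eps = 0)$h)
})
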