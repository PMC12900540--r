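#' Encoder configuration
#'
#' Architecture of the dual-graph variational encoder: a linear embedding of
#' the expression matrix followed, per graph branch, by two shared hidden
#' graph-convolution layers and three parallel third-layer heads emitting the
#' deterministic feature `f` (ReLU), the posterior mean `mu` and the posterior
#' log-variance `log sigma^2` (both linear). Branch outputs are fused per spot
#' by a learned attention weight; the final embedding is `h = [f, z]`.
#'
#' @param input_dim Number of input genes after preprocessing.
#' @param embed_dim Width of the linear embedding (default 128).
#' @param gcn_dims Integer vector of the three per-layer widths
#'   (default `c(64, 32, 32)`); the third entry is the width of `f`, `mu`
#'   and `log sigma^2`, so the fused embedding has width `2 * gcn_dims[3]`.
#' @return A list of class `"encoder_config"`.
#' @export
encoder_config <- function(input_dim, embed_dim = 128, gcn_dims = c(64, 32, 32)) {
  if (length(gcn_dims) != 3) stop("gcn_dims must have exactly 3 entries")
  if (any(c(input_dim, embed_dim, gcn_dims) < 1)) stop("all dims must be >= 1")
  structure(list(input_dim = as.integer(input_dim),
                 embed_dim = as.integer(embed_dim),
                 gcn_dims = as.integer(gcn_dims),
                 latent_dim = as.integer(gcn_dims[3])),
            class = "encoder_config")
}

init_branch <- function(d_in, dims) {
  list(W1 = glorot(d_in, dims[1]), b1 = numeric(dims[1]),
       W2 = glorot(dims[1], dims[2]), b2 = numeric(dims[2]),
       Wf = glorot(dims[2], dims[3]), bf = numeric(dims[3]),
       Wmu = glorot(dims[2], dims[3]), bmu = numeric(dims[3]),
       Wlv = glorot(dims[2], dims[3]) * 0.1, blv = numeric(dims[3]))
}

# Initialize all encoder parameters (uses the current RNG stream; seed
# upstream). branches: "A" (KNN), "P" (PPMI) or both.
init_encoder <- function(cfg, branches = c("A", "P")) {
  dims <- cfg$gcn_dims
  params <- list(
    embed = list(W = glorot(cfg$input_dim, cfg$embed_dim),
                 b = numeric(cfg$embed_dim)),
    branches = stats::setNames(
      lapply(branches, function(b) init_branch(cfg$embed_dim, dims)),
      branches)
  )
  if (length(branches) == 2) {
    params$att <- list(
      f = list(w = stats::rnorm(dims[3], sd = 0.1), b = 0),
      z = list(w = stats::rnorm(dims[3], sd = 0.1), b = 0))
  }
  params
}

#' Linear embedding of the expression matrix
#'
#' Projects the (preprocessed) expression matrix into the encoder's latent
#' input space: `E = X W + b`.
#'
#' @param X `N x G` matrix.
#' @param W `G x d` weight matrix.
#' @param b Length-`d` bias (default zeros).
#' @return `N x d` matrix.
#' @export
linear_embed <- function(X, W, b = NULL) {
  if (ncol(X) != nrow(W))
    stop("shape mismatch: X has ", ncol(X), " columns, W has ", nrow(W), " rows")
  E <- X %*% W
  if (!is.null(b)) E <- sweep(E, 2, b, "+")
  E
}

#' One graph convolution layer
#'
#' The standard propagation rule `sigma(G_hat H W + b)` where `G_hat` is a
#' symmetrically normalized, self-loop-augmented graph matrix (see
#' [normalize_adjacency]). Hidden layers use ReLU; the distribution heads use
#' the identity.
#'
#' @param H `N x d_in` node features.
#' @param Gn `N x N` propagation matrix.
#' @param W `d_in x d_out` weights; `b` optional bias.
#' @param activation `"relu"` or `"identity"`.
#' @return `N x d_out` node features.
#' @export
gcn_layer <- function(H, Gn, W, b = NULL, activation = c("relu", "identity")) {
  activation <- match.arg(activation)
  if (nrow(Gn) != ncol(Gn) || nrow(Gn) != nrow(H))
    stop("propagation matrix must be square and match the node count")
  Z <- Gn %*% H %*% W
  if (!is.null(b)) Z <- sweep(Z, 2, b, "+")
  if (!all(is.finite(Z))) stop("non-finite values in gcn_layer output")
  if (activation == "relu") relu(Z) else Z
}

#' Run one encoder branch
#'
#' Two hidden graph-convolution layers with ReLU, then three parallel heads on
#' the shared second-layer features: `f` (ReLU), `mu` and `log sigma^2`
#' (linear).
#'
#' @param E Embedded features (`N x embed_dim`).
#' @param Gn Propagation matrix for this branch's graph.
#' @param params Branch parameter list (`W1,b1,W2,b2,Wf,bf,Wmu,bmu,Wlv,blv`).
#' @return List with `f`, `mu`, `logvar`.
#' @export
encode_branch <- function(E, Gn, params) {
  H1 <- gcn_layer(E, Gn, params$W1, params$b1, "relu")
  H2 <- gcn_layer(H1, Gn, params$W2, params$b2, "relu")
  list(f = gcn_layer(H2, Gn, params$Wf, params$bf, "relu"),
       mu = gcn_layer(H2, Gn, params$Wmu, params$bmu, "identity"),
       logvar = gcn_layer(H2, Gn, params$Wlv, params$blv, "identity"))
}

#' Reparameterization trick
#'
#' Draws `z = mu + exp(logvar / 2) * eps` with `eps` standard normal, so a
#' stochastic latent sample remains differentiable in `mu` and `logvar`.
#' Passing `eps = 0` gives the deterministic posterior mean used at
#' prediction time.
#'
#' @param mu,logvar Matrices of identical shape.
#' @param eps Optional noise: a matrix shaped like `mu`, the scalar 0, or
#'   `NULL` to draw fresh standard-normal noise from the current RNG stream.
#' @return Matrix `z` shaped like `mu`.
#' @export
reparameterize <- function(mu, logvar, eps = NULL) {
  if (!all(dim(mu) == dim(logvar))) stop("mu and logvar shapes differ")
  if (is.null(eps))
    eps <- matrix(stats::rnorm(length(mu)), nrow(mu), ncol(mu))
  else if (length(eps) == 1)
    eps <- matrix(eps, nrow(mu), ncol(mu))
  mu + exp(logvar / 2) * eps
}

#' Attention fusion of two branch representations
#'
#' Per spot, scores each branch with a shared linear form
#' `s_G = w' u_G + b`, softmax-normalizes the two scores into a weight
#' `alpha` in (0, 1), and returns the convex combination
#' `alpha * uA + (1 - alpha) * uP`.
#'
#' @param uA,uP `N x d` branch features (KNN and PPMI branches).
#' @param w Length-`d` score weights; `b` scalar bias.
#' @return List with `fused` (`N x d`) and `alpha` (length `N`, the weight of
#'   the KNN branch).
#' @export
attention_fuse <- function(uA, uP, w, b = 0) {
  if (!all(dim(uA) == dim(uP))) stop("branch feature widths differ")
  if (length(w) != ncol(uA)) stop("attention weight length != feature width")
  sA <- drop(uA %*% w) + b
  sP <- drop(uP %*% w) + b
  alpha <- sigmoid(sA - sP)  # softmax over two scores
  list(fused = uA * alpha + uP * (1 - alpha), alpha = alpha)
}

# Full encoder forward pass. gmats: named list of propagation matrices
# (subset of A = KNN, P = PPMI). eps: NULL (sample), 0 (deterministic), or a
# named list of per-branch matrices. Returns h plus everything the backward
# pass needs.
encoder_forward <- function(X, gmats, params, eps = 0) {
  E <- linear_embed(X, params$embed$W, params$embed$b)
  brs <- names(params$branches)
  acts <- list()
  for (nm in brs) {
    p <- params$branches[[nm]]
    g <- gmats[[nm]]
    Z1 <- sweep(g %*% E %*% p$W1, 2, p$b1, "+"); H1 <- relu(Z1)
    Z2 <- sweep(g %*% H1 %*% p$W2, 2, p$b2, "+"); H2 <- relu(Z2)
    GH2 <- g %*% H2
    Zf <- sweep(GH2 %*% p$Wf, 2, p$bf, "+"); f <- relu(Zf)
    mu <- sweep(GH2 %*% p$Wmu, 2, p$bmu, "+")
    lv <- sweep(GH2 %*% p$Wlv, 2, p$blv, "+")
    e <- if (is.list(eps)) eps[[nm]]
         else if (is.null(eps)) matrix(stats::rnorm(length(mu)), nrow(mu), ncol(mu))
         else matrix(eps, nrow(mu), ncol(mu))
    sg <- exp(lv / 2)
    z <- mu + sg * e
    acts[[nm]] <- list(Z1 = Z1, H1 = H1, Z2 = Z2, H2 = H2, GH2 = GH2,
                       Zf = Zf, f = f, mu = mu, lv = lv, sigma = sg,
                       eps = e, z = z)
  }
  if (length(brs) == 2) {
    af <- attention_fuse(acts$A$f, acts$P$f, params$att$f$w, params$att$f$b)
    az <- attention_fuse(acts$A$z, acts$P$z, params$att$z$w, params$att$z$b)
    f <- af$fused; z <- az$fused
    alpha_f <- af$alpha; alpha_z <- az$alpha
  } else {
    f <- acts[[brs]]$f; z <- acts[[brs]]$z
    alpha_f <- alpha_z <- rep(1, nrow(f))
  }
  h <- cbind(f, z)
  if (!all(is.finite(h))) stop("non-finite encoder output")
  list(h = h, f = f, z = z, alpha_f = alpha_f, alpha_z = alpha_z,
       E = E, X = X, acts = acts, branches = brs)
}

# Backward pass matching encoder_forward; dh is dLoss/dh. Returns a gradient
# tree with the same shape as params.
encoder_backward <- function(dh, fw, params, gmats) {
  brs <- fw$branches
  d3 <- ncol(fw$f)
  df <- dh[, seq_len(d3), drop = FALSE]
  dz <- dh[, d3 + seq_len(d3), drop = FALSE]
  grads <- list(embed = list(W = params$embed$W * 0,
                             b = params$embed$b * 0),
                branches = list())

  att_back <- function(dfused, uA, uP, alpha, w) {
    duA <- dfused * alpha
    duP <- dfused * (1 - alpha)
    dalpha <- rowSums(dfused * (uA - uP))
    dd <- dalpha * alpha * (1 - alpha)     # wrt score difference sA - sP
    duA <- duA + outer(dd, w)
    duP <- duP - outer(dd, w)
    list(duA = duA, duP = duP, dw = drop(t(uA - uP) %*% dd), db = 0)
  }

  if (length(brs) == 2) {
    bf <- att_back(df, fw$acts$A$f, fw$acts$P$f, fw$alpha_f, params$att$f$w)
    bz <- att_back(dz, fw$acts$A$z, fw$acts$P$z, fw$alpha_z, params$att$z$w)
    dbranch <- list(A = list(df = bf$duA, dz = bz$duA),
                    P = list(df = bf$duP, dz = bz$duP))
    grads$att <- list(f = list(w = bf$dw, b = bf$db),
                      z = list(w = bz$dw, b = bz$db))
  } else {
    dbranch <- stats::setNames(list(list(df = df, dz = dz)), brs)
  }

  dE <- fw$E * 0
  for (nm in brs) {
    p <- params$branches[[nm]]
    a <- fw$acts[[nm]]
    g <- gmats[[nm]]
    dmu <- dbranch[[nm]]$dz
    dlv <- dbranch[[nm]]$dz * a$eps * a$sigma * 0.5
    dZf <- dbranch[[nm]]$df * (a$Zf > 0)
    gW <- list(
      Wf = t(a$GH2) %*% dZf, bf = colSums(dZf),
      Wmu = t(a$GH2) %*% dmu, bmu = colSums(dmu),
      Wlv = t(a$GH2) %*% dlv, blv = colSums(dlv))
    dH2 <- t(g) %*% (dZf %*% t(p$Wf) + dmu %*% t(p$Wmu) + dlv %*% t(p$Wlv))
    dZ2 <- dH2 * (a$Z2 > 0)
    GH1 <- g %*% a$H1
    gW$W2 <- t(GH1) %*% dZ2; gW$b2 <- colSums(dZ2)
    dH1 <- t(g) %*% (dZ2 %*% t(p$W2))
    dZ1 <- dH1 * (a$Z1 > 0)
    GE <- g %*% fw$E
    gW$W1 <- t(GE) %*% dZ1; gW$b1 <- colSums(dZ1)
    dE <- dE + t(g) %*% (dZ1 %*% t(p$W1))
    grads$branches[[nm]] <- gW[names(params$branches[[nm]])]
  }
  grads$embed$W <- t(fw$X) %*% dE
  grads$embed$b <- colSums(dE)
  # order the gradient tree exactly like the parameter tree
  grads <- grads[names(params)]
  grads
}
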