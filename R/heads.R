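#' Cluster classifier configuration
#'
#' A stack of residual blocks (each `h + ReLU(BN(W h))`) followed by a linear
#' layer and softmax over the `C` region classes. The `"mlp"` variant replaces
#' the residual blocks with plain dense ReLU layers of the same width (no
#' batch norm, no skip connection) and is the ablation comparator.
#'
#' @param n_classes Number of region classes `C` (>= 2).
#' @param width Feature width (must equal the encoder's embedding width).
#' @param n_blocks Number of residual (or dense) blocks, default 2.
#' @param bn_momentum Running-statistics update rate for batch norm
#'   (default 0.1).
#' @param bn_eps Batch-norm variance floor (default 1e-5).
#' @param variant `"residual"` (default) or `"mlp"`.
#' @return A list of class `"classifier_config"`.
#' @export
classifier_config <- function(n_classes, width, n_blocks = 2,
                              bn_momentum = 0.1, bn_eps = 1e-5,
                              variant = c("residual", "mlp")) {
  variant <- match.arg(variant)
  if (n_classes < 2) stop("need at least 2 classes")
  if (n_blocks < 1) stop("n_blocks must be >= 1")
  structure(list(n_classes = as.integer(n_classes), width = as.integer(width),
                 n_blocks = as.integer(n_blocks), bn_momentum = bn_momentum,
                 bn_eps = bn_eps, variant = variant),
            class = "classifier_config")
}

init_classifier <- function(cfg) {
  w <- cfg$width
  blocks <- lapply(seq_len(cfg$n_blocks), function(i) {
    if (cfg$variant == "residual")
      list(W = glorot(w, w), gamma = rep(1, w), beta = numeric(w))
    else
      list(W = glorot(w, w), b = numeric(w))
  })
  list(blocks = blocks,
       out = list(W = glorot(w, cfg$n_classes), b = numeric(cfg$n_classes)))
}

init_bn_state <- function(cfg) {
  if (cfg$variant != "residual") return(list())
  lapply(seq_len(cfg$n_blocks),
         function(i) list(mean = NULL, var = NULL))
}

bn_forward <- function(pre, gamma, beta, state, mode, momentum, eps) {
  if (mode == "train") {
    mu <- colMeans(pre)
    va <- colMeans(sweep(pre, 2, mu, "-")^2)   # biased batch variance
    if (is.null(state$mean)) {
      state$mean <- mu; state$var <- va
    } else {
      state$mean <- (1 - momentum) * state$mean + momentum * mu
      state$var <- (1 - momentum) * state$var + momentum * va
    }
  } else {
    if (is.null(state$mean))
      stop("batch norm used in eval mode before any training step")
    mu <- state$mean; va <- state$var
  }
  inv <- 1 / sqrt(va + eps)
  xhat <- sweep(sweep(pre, 2, mu, "-"), 2, inv, "*")
  out <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  list(out = out, xhat = xhat, inv = inv, state = state)
}

bn_backward <- function(dout, xhat, inv, gamma, mode) {
  dgamma <- colSums(dout * xhat)
  dbeta <- colSums(dout)
  dxhat <- sweep(dout, 2, gamma, "*")
  if (mode == "train") {
    n <- nrow(dout)
    dpre <- sweep(
      dxhat - matrix(colMeans(dxhat), n, ncol(dout), byrow = TRUE) -
        xhat * matrix(colMeans(dxhat * xhat), n, ncol(dout), byrow = TRUE),
      2, inv, "*")
  } else {
    dpre <- sweep(dxhat, 2, inv, "*")
  }
  list(dpre = dpre, dgamma = dgamma, dbeta = dbeta)
}

#' Apply one residual block
#'
#' `out = h + ReLU(BN(h W))`: a linear map, batch normalization (batch
#' statistics in train mode, running statistics in eval mode), ReLU, and a
#' skip connection. The ReLU branch is elementwise non-negative, so the block
#' can only add to its input.
#'
#' @param h `N x width` feature rows.
#' @param params List with `W`, `gamma`, `beta`.
#' @param bn_state List with running `mean` and `var` (`NULL` before the first
#'   train-mode call).
#' @param mode `"train"` or `"eval"`.
#' @param bn_momentum,bn_eps Batch-norm constants.
#' @return List with `out`, and the updated `bn_state`.
#' @export
residual_block <- function(h, params, bn_state = list(mean = NULL, var = NULL),
                           mode = c("train", "eval"),
                           bn_momentum = 0.1, bn_eps = 1e-5) {
  mode <- match.arg(mode)
  if (ncol(h) != nrow(params$W)) stop("feature width != block width")
  pre <- h %*% params$W
  bn <- bn_forward(pre, params$gamma, params$beta, bn_state, mode,
                   bn_momentum, bn_eps)
  list(out = h + relu(bn$out), bn_state = bn$state)
}

# Classifier forward pass with full cache for backprop.
classifier_forward <- function(h, params, cfg, bn_state, mode) {
  caches <- list()
  cur <- h
  for (i in seq_along(params$blocks)) {
    p <- params$blocks[[i]]
    if (cfg$variant == "residual") {
      pre <- cur %*% p$W
      bn <- bn_forward(pre, p$gamma, p$beta, bn_state[[i]], mode,
                       cfg$bn_momentum, cfg$bn_eps)
      bn_state[[i]] <- bn$state
      act <- relu(bn$out)
      caches[[i]] <- list(input = cur, xhat = bn$xhat, inv = bn$inv,
                          bnout = bn$out)
      cur <- cur + act
    } else {
      pre <- sweep(cur %*% p$W, 2, p$b, "+")
      caches[[i]] <- list(input = cur, pre = pre)
      cur <- relu(pre)
    }
  }
  logits <- sweep(cur %*% params$out$W, 2, params$out$b, "+")
  probs <- softmax_rows(logits)
  list(logits = logits, probs = probs, top = cur, caches = caches,
       bn_state = bn_state, mode = mode)
}

# Backward pass; dlogits is dLoss/dlogits. Returns grads and dh.
classifier_backward <- function(dlogits, fw, params, cfg) {
  grads <- list(blocks = vector("list", length(params$blocks)),
                out = list(W = t(fw$top) %*% dlogits,
                           b = colSums(dlogits)))
  dcur <- dlogits %*% t(params$out$W)
  for (i in rev(seq_along(params$blocks))) {
    p <- params$blocks[[i]]
    cc <- fw$caches[[i]]
    if (cfg$variant == "residual") {
      dact <- dcur * (cc$bnout > 0)
      bb <- bn_backward(dact, cc$xhat, cc$inv, p$gamma, fw$mode)
      grads$blocks[[i]] <- list(W = t(cc$input) %*% bb$dpre,
                                gamma = bb$dgamma, beta = bb$dbeta)
      dcur <- dcur + bb$dpre %*% t(p$W)
    } else {
      dpre <- dcur * (cc$pre > 0)
      grads$blocks[[i]] <- list(W = t(cc$input) %*% dpre,
                                b = colSums(dpre))
      dcur <- dpre %*% t(p$W)
    }
  }
  list(grads = grads, dh = dcur)
}

#' Class probabilities from the cluster classifier
#'
#' Evaluation-mode forward pass through the residual (or MLP) classifier:
#' each row is a probability distribution over the `C` classes. Predicted
#' labels are the per-row argmax with ties resolved to the lowest class index.
#'
#' @param h `N x width` embeddings.
#' @param params Classifier parameters (from training).
#' @param cfg The [classifier_config].
#' @param bn_state Batch-norm running statistics (from training).
#' @return `N x C` probability matrix.
#' @export
classify <- function(h, params, cfg, bn_state) {
  classifier_forward(h, params, cfg, bn_state, "eval")$probs
}

#' Multiclass cross-entropy loss
#'
#' `L = -(1/N) sum_i sum_c y_ic log(yhat_ic)` with natural log and one-hot
#' truth; zero iff every true-class probability is 1. True-class
#' probabilities are clamped at 1e-12 (with a warning) before the log.
#'
#' @param probs `N x C` predicted probability matrix.
#' @param y_onehot `N x C` one-hot truth matrix.
#' @return Non-negative scalar.
#' @export
cross_entropy_loss <- function(probs, y_onehot) {
  if (!all(dim(probs) == dim(y_onehot))) stop("shape mismatch")
  # with one-hot truth only the true-class probability enters the sum, so
  # clamp (and warn) on that value alone
  -mean(clamped_log(rowSums(probs * y_onehot)))
}

init_discriminator <- function(width, hidden = c(64, 32)) {
  list(W1 = glorot(width, hidden[1]), b1 = numeric(hidden[1]),
       W2 = glorot(hidden[1], hidden[2]), b2 = numeric(hidden[2]),
       W3 = glorot(hidden[2], 1), b3 = 0)
}

disc_forward <- function(h, params) {
  Z1 <- sweep(h %*% params$W1, 2, params$b1, "+"); H1 <- relu(Z1)
  Z2 <- sweep(H1 %*% params$W2, 2, params$b2, "+"); H2 <- relu(Z2)
  logit <- drop(H2 %*% params$W3) + params$b3
  list(p = sigmoid(logit), logit = logit,
       h = h, Z1 = Z1, H1 = H1, Z2 = Z2, H2 = H2)
}

# dlogit: dLoss/dlogit (length N). Returns grads and dh.
disc_backward <- function(dlogit, fw, params) {
  dH2 <- outer(dlogit, drop(params$W3))
  dZ2 <- dH2 * (fw$Z2 > 0)
  dH1 <- dZ2 %*% t(params$W2)
  dZ1 <- dH1 * (fw$Z1 > 0)
  grads <- list(W1 = t(fw$h) %*% dZ1, b1 = colSums(dZ1),
                W2 = t(fw$H1) %*% dZ2, b2 = colSums(dZ2),
                W3 = t(fw$H2) %*% cbind(dlogit), b3 = sum(dlogit))
  list(grads = grads, dh = dZ1 %*% t(params$W1))
}

#' Domain membership probability
#'
#' Forward pass through the domain discriminator: a small feed-forward network
#' ending in a sigmoid. Outputs are strictly inside (0, 1); 1 means "source
#' domain", 0 means "target domain".
#'
#' @param h `N x width` embeddings.
#' @param params Discriminator parameters.
#' @return Length-`N` vector of probabilities.
#' @export
discriminate <- function(h, params) disc_forward(h, params)$p

#' Domain-discriminator loss
#'
#' Binary cross-entropy for the source-vs-target discrimination task:
#' `L_D = -mean(log d_s) - mean(log(1 - d_t))` (natural log). Minimized by a
#' perfect discriminator; equals `2 log 2` at the fooled equilibrium
#' `d = 0.5`.
#'
#' @param d_s Discriminator outputs on source embeddings.
#' @param d_t Discriminator outputs on target embeddings.
#' @return Scalar loss.
#' @export
discriminator_loss <- function(d_s, d_t) {
  if (!length(d_s) || !length(d_t)) stop("empty discriminator outputs")
  -mean(clamped_log(d_s)) - mean(clamped_log(1 - d_t))
}

#' Adversarial generator loss for the target encoder
#'
#' Non-saturating objective `L_G = -mean(log d_t)`: the target encoder is
#' rewarded when the discriminator assigns its embeddings to the source
#' domain.
#'
#' @param d_t Discriminator outputs on target embeddings.
#' @return Scalar loss.
#' @export
generator_loss <- function(d_t) {
  if (!length(d_t)) stop("empty discriminator outputs")
  -mean(clamped_log(d_t))
}
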