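# Internal numerical helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's RNG
# stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

relu <- function(x) pmax(x, 0)

sigmoid <- function(x) 1 / (1 + exp(-x))

# log with the probability clamped away from 0 (numerical safety in all
# cross-entropy style losses); warns when clamping actually fires.
clamped_log <- function(p, eps = 1e-12, warn = TRUE) {
  if (warn && any(p < eps))
    warning("probabilities clamped at ", eps, " inside log")
  log(pmax(p, eps))
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

one_hot <- function(labels, classes) {
  y <- matrix(0, length(labels), length(classes),
              dimnames = list(NULL, classes))
  j <- match(as.character(labels), classes)
  if (anyNA(j)) stop("labels outside the class set: ",
                     paste(unique(labels[is.na(j)]), collapse = ", "))
  y[cbind(seq_along(j), j)] <- 1
  y
}

# ---- parameter trees -------------------------------------------------------
# All model parameters live in nested named lists whose leaves are numeric
# vectors/matrices; these helpers walk two trees in parallel.

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

map_params <- function(f, a) {
  if (is.list(a)) lapply(a, function(x) map_params(f, x)) else f(a)
}

map2_params <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- map2_params(f, a[[i]], b[[i]])
    out
  } else f(a, b)
}

zeros_like <- function(a) map_params(function(x) x * 0, a)

# ---- Adam optimizer --------------------------------------------------------

adam_init <- function(params) {
  list(m = zeros_like(params), v = zeros_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- map2_params(function(m, g) beta1 * m + (1 - beta1) * g,
                         state$m, grads)
  state$v <- map2_params(function(v, g) beta2 * v + (1 - beta2) * g^2,
                         state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- map2_params(function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps),
                     state$m, state$v)
  params <- map2_params(`-`, params, upd)
  list(params = params, state = state)
}
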