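# Shared fixtures and slow-run cache. Heavy end-to-end fits on the default
# synthetic pair are computed once per test session and reused across files.

.run_cache <- new.env(parent = emptyenv())

default_pair <- function() {
  if (is.null(.run_cache$pair))
    .run_cache$pair <- generate_slice_pair(synthetic_config())
  .run_cache$pair
}

# key: one of "on", "off", "knn", "ppmi"
default_fit <- function(key) {
  if (!is.null(.run_cache[[key]])) return(.run_cache[[key]])
  pair <- default_pair()
  fit <- switch(key,
    on = stransfer(pair$source, pair$target),
    off = stransfer(pair$source, pair$target, adapt = FALSE),
    knn = stransfer(pair$source, pair$target, graph_mode = "knn"),
    ppmi = stransfer(pair$source, pair$target, graph_mode = "ppmi"),
    stop("unknown fit key: ", key))
  .run_cache[[key]] <- fit
  fit
}

# small labeled slice for fast unit tests
tiny_slice <- function(n = 12, g = 6, seed = 42) {
  set.seed(seed)
  x <- matrix(rpois(n * g, 5) + 1, n, g)
  coords <- cbind(runif(n), runif(n))
  labels <- rep(c("a", "b"), length.out = n)
  st_slice(x, coords, labels = labels, slice_id = "tiny")
}

# small graph inputs for encoder tests
tiny_graph_mats <- function(n = 6, k = 2, seed = 7) {
  set.seed(seed)
  coords <- cbind(runif(n), runif(n))
  a <- build_knn_adjacency(coords, k)
  p <- compute_ppmi(cooccurrence(a, walk_config(2)))
  list(A = normalize_adjacency(a), P = normalize_adjacency(p))
}

# brute-force expected co-occurrence: explicit enumeration of every walk of
# length <= T, accumulating visit probabilities step by step
enum_cooccurrence <- function(adj, T) {
  n <- nrow(adj)
  f <- matrix(0, n, n)
  visit <- function(start, node, prob, depth) {
    if (depth == T) return()
    nb <- which(adj[node, ] > 0)
    for (j in nb) {
      pj <- prob / length(nb)
      f[start, j] <<- f[start, j] + pj
      visit(start, j, pj, depth + 1)
    }
  }
  for (i in seq_len(n)) visit(i, i, 1, 0)
  f / T
}

is_connected_graph <- function(adj) {
  n <- nrow(adj)
  seen <- c(1L)
  frontier <- c(1L)
  while (length(frontier)) {
    nxt <- setdiff(which(colSums(adj[frontier, , drop = FALSE]) > 0), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  length(seen) == n
}
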