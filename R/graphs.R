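#' Random-walk configuration for the co-occurrence graph
#'
#' Controls the truncated random walks used to turn the KNN spatial graph into
#' a node co-occurrence matrix, from which the positive pointwise mutual
#' information (PPMI) graph is computed.
#'
#' @param walk_length Truncation horizon `T` (>= 1): walks of length 1..T are
#'   accounted for. Default 3, matching the three-layer receptive field of the
#'   graph convolutional encoder.
#' @param mode `"expected"` (default) computes the exact expected visit
#'   frequencies, `(1/T) * sum_{t=1..T} Pi^t` with `Pi` the row-normalized
#'   adjacency — deterministic and reproducible. `"sampled"` simulates actual
#'   walks and tallies empirical co-occurrence.
#' @param walks_per_node Number of simulated walks per start node (sampled
#'   mode).
#' @param seed RNG seed for sampled mode.
#' @return A list of class `"walk_config"`.
#' @export
walk_config <- function(walk_length = 3, mode = c("expected", "sampled"),
                        walks_per_node = 100, seed = 0) {
  mode <- match.arg(mode)
  if (walk_length < 1) stop("walk_length must be >= 1")
  if (mode == "sampled" && walks_per_node < 1)
    stop("walks_per_node must be >= 1 in sampled mode")
  structure(list(walk_length = as.integer(walk_length), mode = mode,
                 walks_per_node = as.integer(walks_per_node),
                 seed = as.integer(seed)),
            class = "walk_config")
}

#' Build the k-nearest-neighbour spatial adjacency
#'
#' Connects each spot to its `k` nearest neighbours in planar Euclidean
#' distance (self excluded; distance ties broken by lower spot index) and
#' symmetrizes the directed relation by logical OR. The result is the binary
#' adjacency matrix `A` encoding local spatial connectivity.
#'
#' @param coords `N x 2` numeric matrix of spot positions.
#' @param k Number of neighbours, `1 <= k <= N - 1`.
#' @return `N x N` binary symmetric matrix with zero diagonal.
#' @export
#' @examples
#' build_knn_adjacency(cbind(c(0, 1), c(0, 0)), k = 1)
build_knn_adjacency <- function(coords, k) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 2) stop("need at least 2 spots")
  if (k < 1 || k >= n) stop("k must satisfy 1 <= k <= N - 1 (k = ", k,
                            ", N = ", n, ")")
  if (!all(is.finite(coords))) stop("coords must be finite")
  d <- as.matrix(stats::dist(coords))
  a <- matrix(0, n, n)
  idx <- seq_len(n)
  for (i in idx) {
    di <- d[i, ]
    di[i] <- Inf
    nb <- order(di, idx)[seq_len(k)]  # ties -> lower index
    a[i, nb] <- 1
  }
  a <- pmax(a, t(a))
  diag(a) <- 0
  a
}

#' Expected or sampled co-occurrence frequencies from truncated random walks
#'
#' Starting from a symmetric adjacency, performs truncated random walks of
#' length up to `T` and returns the `N x N` matrix of visit frequencies
#' `F[i, j]`: how often a walk started at `i` occupies `j` within the horizon.
#' In expected mode this is computed in closed form as the average of the
#' first `T` powers of the row-stochastic transition matrix; in sampled mode
#' it is tallied from simulated walks (and converges to the expected form as
#' the number of walks grows).
#'
#' @param adjacency Symmetric non-negative matrix with no all-zero row.
#' @param cfg A [walk_config].
#' @return `N x N` non-negative matrix; rows sum to 1 in expected mode.
#' @export
cooccurrence <- function(adjacency, cfg = walk_config()) {
  a <- as.matrix(adjacency)
  n <- nrow(a)
  if (n != ncol(a)) stop("adjacency must be square")
  if (!isTRUE(all.equal(a, t(a)))) stop("adjacency must be symmetric")
  deg <- rowSums(a)
  if (any(deg == 0))
    stop("adjacency has isolated node(s) (all-zero row); rebuild the graph ",
         "with a larger k")
  trans <- a / deg
  tlen <- cfg$walk_length
  if (cfg$mode == "expected") {
    acc <- matrix(0, n, n)
    pw <- diag(n)
    for (t in seq_len(tlen)) {
      pw <- pw %*% trans
      acc <- acc + pw
    }
    return(acc / tlen)
  }
  # sampled: simulate walks_per_node walks of length tlen from each node
  counts <- matrix(0, n, n)
  with_seed(cfg$seed, {
    for (i in seq_len(n)) {
      for (w in seq_len(cfg$walks_per_node)) {
        cur <- i
        for (t in seq_len(tlen)) {
          nb <- which(a[cur, ] > 0)
          cur <- if (length(nb) == 1) nb else
            sample(nb, 1, prob = a[cur, nb])
          counts[i, cur] <- counts[i, cur] + 1
        }
      }
    }
  })
  counts / (cfg$walks_per_node * tlen)
}

#' Positive pointwise mutual information of a co-occurrence matrix
#'
#' Converts raw co-occurrence frequencies into the PPMI graph
#' `p_ij = max(0, log P(i,j) / (P(i) P(j)))` (natural log), where `P(i,j)` is
#' the joint occupancy probability and `P(i)`, `P(j)` its marginals. Cells
#' with zero co-occurrence stay exactly zero (never `-Inf`), the frequency
#' matrix is symmetrized as `(F + F')/2` before the ratio so the output is
#' symmetric, and the diagonal is zeroed (self-affinity re-enters through the
#' self-loop added during normalization). PPMI highlights pairs that co-occur
#' more than independence would predict, i.e. long-range structural
#' association beyond direct spatial proximity.
#'
#' @param freq `N x N` elementwise non-negative matrix with positive total.
#' @return `N x N` symmetric non-negative PPMI matrix with zero diagonal.
#' @export
#' @examples
#' compute_ppmi(matrix(c(0, 1, 1, 0), 2, 2))  # off-diagonals log(2)
compute_ppmi <- function(freq) {
  f <- as.matrix(freq)
  if (any(f < 0)) stop("freq must be elementwise non-negative")
  if (sum(f) <= 0) stop("freq has zero grand total")
  f <- (f + t(f)) / 2
  joint <- f / sum(f)
  pi_ <- rowSums(joint)
  pj_ <- colSums(joint)
  ratio <- joint / outer(pi_, pj_)
  p <- ifelse(joint > 0, pmax(0, log(ratio)), 0)
  diag(p) <- 0
  p
}

#' Symmetric normalization of a graph matrix for convolution
#'
#' Adds self-loops and applies the symmetric degree normalization
#' `D^(-1/2) (G + I) D^(-1/2)` used by graph convolutional layers. The
#' self-loop guarantees every degree is positive, so the operation is defined
#' for any non-negative square matrix including the zero matrix.
#'
#' @param graph_matrix Square elementwise non-negative matrix (binary KNN
#'   adjacency or weighted PPMI matrix).
#' @return The normalized propagation matrix; symmetric when the input is.
#' @export
normalize_adjacency <- function(graph_matrix) {
  g <- as.matrix(graph_matrix)
  if (nrow(g) != ncol(g)) stop("graph_matrix must be square")
  if (any(g < 0)) stop("graph_matrix must be elementwise non-negative")
  gt <- g + diag(nrow(g))
  dinv <- 1 / sqrt(rowSums(gt))
  gt * outer(dinv, dinv)
}

#' Build both spatial graphs for a slice
#'
#' Convenience wrapper: KNN adjacency from the slice coordinates, truncated
#' random-walk co-occurrence, PPMI matrix, and the normalized propagation
#' matrices for both graphs.
#'
#' @param slice An [st_slice] (or a bare `N x 2` coordinate matrix).
#' @param k Neighbour count for the KNN graph (default 6, the hexagonal
#'   neighbourhood of Visium arrays).
#' @param walk A [walk_config].
#' @return An object of class `"spatial_graph"`: list with `knn_adjacency`,
#'   `ppmi`, `knn_norm`, `ppmi_norm`, `k`, `walk_cfg`.
#' @export
spatial_graph <- function(slice, k = 6, walk = walk_config()) {
  coords <- if (inherits(slice, "st_slice")) slice$coords else as.matrix(slice)
  a <- build_knn_adjacency(coords, k)
  f <- cooccurrence(a, walk)
  p <- compute_ppmi(f)
  structure(list(knn_adjacency = a, ppmi = p,
                 knn_norm = normalize_adjacency(a),
                 ppmi_norm = normalize_adjacency(p),
                 k = as.integer(k), walk_cfg = walk),
            class = "spatial_graph")
}

#' @export
print.spatial_graph <- function(x, ...) {
  n <- nrow(x$knn_adjacency)
  cat("spatial_graph: ", n, " spots, k = ", x$k,
      ", walk T = ", x$walk_cfg$walk_length, " (", x$walk_cfg$mode, ")\n",
      "  KNN edges: ", sum(x$knn_adjacency) / 2,
      "; PPMI nonzeros: ", sum(x$ppmi > 0), "\n", sep = "")
  invisible(x)
}

#' Export a slice's graphs as Matrix Market files
#'
#' Writes the binary KNN adjacency and the PPMI matrix as sparse `.mtx`
#' files plus a plain-text spot-id index.
#'
#' @param graph A [spatial_graph].
#' @param spot_ids Character vector of spot identifiers.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the written paths.
#' @export
export_graph_mtx <- function(graph, spot_ids, out_dir) {
  stopifnot(inherits(graph, "spatial_graph"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pa <- file.path(out_dir, "knn_adjacency.mtx")
  pp <- file.path(out_dir, "ppmi.mtx")
  pi_ <- file.path(out_dir, "spot_index.txt")
  Matrix::writeMM(methods::as(Matrix::Matrix(graph$knn_adjacency, sparse = TRUE),
                              "generalMatrix"), pa)
  Matrix::writeMM(methods::as(Matrix::Matrix(graph$ppmi, sparse = TRUE),
                              "generalMatrix"), pp)
  writeLines(as.character(spot_ids), pi_)
  invisible(c(pa, pp, pi_))
}
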