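#' Synthetic slice-pair configuration
#'
#' Parameters of the built-in generator of paired source/target slices with
#' spatially contiguous domains, domain-specific marker expression and a
#' controllable inter-slice batch effect. Defaults describe the package's
#' reference simulation: 400 spots, 60 genes, 4 layered domains with 5 marker
#' genes each shifted by 2 natural-log units, log-noise 0.6, and a batch
#' effect multiplying half the genes of the target slice by gene-wise
#' log-normal factors with log-sd 1.
#'
#' @param n_spots Spots per slice.
#' @param n_genes Genes.
#' @param n_domains Number of spatial domains `C` (>= 2).
#' @param layout `"strips"` (layered bands, cortex-like) or `"blobs"`
#'   (Gaussian patches).
#' @param markers_per_domain Marker genes per domain
#'   (`n_domains * markers_per_domain <= n_genes`).
#' @param effect_size Log-scale mean shift `delta` added to a domain's marker
#'   genes in member spots.
#' @param noise_sd Log-scale expression noise standard deviation.
#' @param batch_shift Log-sd `delta_b` of the gene-wise multiplicative batch
#'   factors applied to the target slice (0 = identical platforms).
#' @param batch_frac Fraction of genes affected by the batch effect.
#' @param coordinate_jitter Uniform jitter amplitude on the grid coordinates
#'   (grid-spacing units).
#' @param count_model `"lognormal"` (rounded log-normal; closed-form moments)
#'   or `"nb"` (negative binomial with matching log-means, for realism
#'   checks).
#' @param nb_size Negative-binomial size (dispersion) when
#'   `count_model = "nb"`.
#' @param seed RNG seed for the pair.
#' @return A list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_spots = 400, n_genes = 60, n_domains = 4,
                             layout = c("strips", "blobs"),
                             markers_per_domain = 5, effect_size = 2,
                             noise_sd = 0.6, batch_shift = 1.0,
                             batch_frac = 0.5, coordinate_jitter = 0.15,
                             count_model = c("lognormal", "nb"),
                             nb_size = 10, seed = 0) {
  layout <- match.arg(layout)
  count_model <- match.arg(count_model)
  if (n_domains < 2) stop("n_domains must be >= 2")
  if (n_spots < n_domains) stop("n_spots must be >= n_domains")
  if (n_domains * markers_per_domain > n_genes)
    stop("n_domains * markers_per_domain exceeds n_genes")
  if (effect_size < 0 || noise_sd < 0 || batch_shift < 0)
    stop("effect_size, noise_sd and batch_shift must be >= 0")
  structure(list(n_spots = as.integer(n_spots), n_genes = as.integer(n_genes),
                 n_domains = as.integer(n_domains), layout = layout,
                 markers_per_domain = as.integer(markers_per_domain),
                 effect_size = effect_size, noise_sd = noise_sd,
                 batch_shift = batch_shift, batch_frac = batch_frac,
                 coordinate_jitter = coordinate_jitter,
                 count_model = count_model, nb_size = nb_size,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate spot coordinates and domain labels
#'
#' `"strips"` places spots on a jittered square grid and assigns domains by
#' quantile bands of the y coordinate — contiguous layered regions like
#' cortical layers. `"blobs"` spreads domain centers on a circle and samples
#' each domain's spots around its center. Every domain is guaranteed at least
#' one spot. Uses the current RNG stream.
#'
#' @param cfg A [synthetic_config].
#' @return List with `coords` (`N x 2`) and `labels` (character,
#'   `"R1".."RC"`).
#' @export
generate_layout <- function(cfg) {
  n <- cfg$n_spots
  C <- cfg$n_domains
  if (cfg$layout == "strips") {
    nx <- ceiling(sqrt(n))
    ny <- ceiling(n / nx)
    grid <- expand.grid(x = seq_len(nx), y = seq_len(ny))[seq_len(n), ]
    jit <- cfg$coordinate_jitter
    coords <- cbind(grid$x + stats::runif(n, -jit, jit),
                    grid$y + stats::runif(n, -jit, jit))
    qs <- stats::quantile(coords[, 2], probs = seq(0, 1, length.out = C + 1))
    band <- cut(coords[, 2], breaks = qs, include.lowest = TRUE,
                labels = FALSE)
    labels <- paste0("R", band)
  } else {
    ang <- 2 * pi * (seq_len(C) - 1) / C
    centers <- cbind(cos(ang), sin(ang)) * 2
    sizes <- rep(n %/% C, C)
    sizes[seq_len(n %% C)] <- sizes[seq_len(n %% C)] + 1
    coords <- NULL
    labels <- character(0)
    for (c in seq_len(C)) {
      coords <- rbind(coords,
                      cbind(stats::rnorm(sizes[c], centers[c, 1], 0.6),
                            stats::rnorm(sizes[c], centers[c, 2], 0.6)))
      labels <- c(labels, rep(paste0("R", c), sizes[c]))
    }
  }
  stopifnot(all(paste0("R", seq_len(C)) %in% labels))
  list(coords = unname(as.matrix(coords)), labels = labels)
}

# Marker gene indices per domain: consecutive blocks at the head of the panel.
marker_sets <- function(cfg) {
  lapply(seq_len(cfg$n_domains), function(c)
    (c - 1) * cfg$markers_per_domain + seq_len(cfg$markers_per_domain))
}

#' Generate an expression matrix for labeled spots
#'
#' Log-normal model: baseline gene log-means are standard normal (shared via
#' `base_logmean` when generating paired slices), each domain's marker genes
#' get `+effect_size` added to their log-mean in member spots, per-spot
#' log-expression adds `N(0, noise_sd^2)` noise, and values are exponentiated
#' and rounded to counts (`"nb"` model instead draws negative-binomial counts
#' with the same log-means). Uses the current RNG stream.
#'
#' @param labels Character vector of domain labels (`"R1"..."RC"`).
#' @param cfg A [synthetic_config].
#' @param base_logmean Optional length-`G` baseline log-means (drawn if
#'   missing).
#' @param round_counts Round to integer counts (default TRUE).
#' @return `N x G` expression matrix.
#' @export
generate_expression <- function(labels, cfg, base_logmean = NULL,
                                round_counts = TRUE) {
  n <- length(labels)
  g <- cfg$n_genes
  if (is.null(base_logmean)) base_logmean <- stats::rnorm(g)
  mk <- marker_sets(cfg)
  lm <- matrix(base_logmean, n, g, byrow = TRUE)
  dom <- as.integer(sub("^R", "", labels))
  for (c in seq_len(cfg$n_domains)) {
    rows <- which(dom == c)
    lm[rows, mk[[c]]] <- lm[rows, mk[[c]]] + cfg$effect_size
  }
  if (cfg$count_model == "nb") {
    x <- matrix(stats::rnbinom(n * g, size = cfg$nb_size, mu = exp(lm)), n, g)
    return(x)
  }
  x <- exp(lm + matrix(stats::rnorm(n * g, 0, cfg$noise_sd), n, g))
  if (round_counts) x <- round(x)
  x
}

#' Apply a gene-wise multiplicative batch effect
#'
#' Scales a seeded random subset (`batch_frac`) of genes by per-gene factors
#' `exp(N(0, batch_shift^2))`, shared across spots — the library/platform
#' style shift that separates slices measured under different conditions.
#' With `batch_shift = 0` or `batch_frac = 0` the matrix is returned
#' unchanged. Uses the current RNG stream.
#'
#' @param X Non-negative expression matrix.
#' @param cfg A [synthetic_config].
#' @return Shifted expression matrix of the same shape.
#' @export
apply_batch_effect <- function(X, cfg) {
  if (any(X < 0)) stop("expression must be non-negative")
  g <- ncol(X)
  n_aff <- floor(cfg$batch_frac * g)
  if (n_aff == 0 || cfg$batch_shift == 0) {
    # consume the same RNG draws either way so downstream streams align
    if (n_aff > 0) { sample.int(g, n_aff); stats::rnorm(n_aff) }
    return(X)
  }
  sel <- sample.int(g, n_aff)
  fac <- exp(stats::rnorm(n_aff, 0, cfg$batch_shift))
  X[, sel] <- sweep(X[, sel, drop = FALSE], 2, fac, "*")
  X
}

#' Generate a paired source/target slice set
#'
#' Draws two independent slices from the same generative law (shared baseline
#' gene log-means and marker structure; fresh layouts and noise), applies the
#' batch effect to the target, and returns both as [st_slice] objects. The
#' target's labels are retained for evaluation only and flagged with
#' attribute `"held_out"`.
#'
#' @param cfg A [synthetic_config].
#' @return List with `source` and `target` slices (both labeled; target's
#'   labels carry `attr(, "held_out") = TRUE`).
#' @export
#' @examples
#' pair <- generate_slice_pair(synthetic_config(n_spots = 80, n_genes = 20,
#'                                              markers_per_domain = 4))
#' pair$source
generate_slice_pair <- function(cfg = synthetic_config()) {
  with_seed(cfg$seed, {
    base_lm <- stats::rnorm(cfg$n_genes)
    lay_s <- generate_layout(cfg)
    xs <- generate_expression(lay_s$labels, cfg, base_lm)
    lay_t <- generate_layout(cfg)
    xt <- generate_expression(lay_t$labels, cfg, base_lm)
    xt <- apply_batch_effect(xt, cfg)
    gene_ids <- sprintf("gene_%02d", seq_len(cfg$n_genes))
    source <- st_slice(xs, lay_s$coords, labels = lay_s$labels,
                       spot_ids = sprintf("s_%04d", seq_len(cfg$n_spots)),
                       gene_ids = gene_ids, slice_id = "synthetic_source")
    target <- st_slice(xt, lay_t$coords, labels = lay_t$labels,
                       spot_ids = sprintf("t_%04d", seq_len(cfg$n_spots)),
                       gene_ids = gene_ids, slice_id = "synthetic_target")
    attr(target$labels, "held_out") <- TRUE
    list(source = source, target = target)
  })
}
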