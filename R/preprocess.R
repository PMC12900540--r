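#' Expression preprocessing configuration
#'
#' Standard single-cell/spatial preprocessing recipe: total-count
#' normalization, log transform, highly-variable-gene selection and per-gene
#' standardization. The defaults suit Visium-scale panels; targeted panels
#' with few genes should set `n_hvg = 0` to keep every gene.
#'
#' @param target_sum Library size each spot is rescaled to before the log
#'   transform (default 1e4). Set `NULL` to skip normalization.
#' @param log1p Apply `log(1 + x)` after normalization.
#' @param n_hvg Number of highly variable genes to retain, ranked by the
#'   variance-to-mean dispersion of the log-normalized matrix; `0` keeps all.
#' @param scale Standardize each gene to zero mean, unit variance.
#' @param clip Cap absolute standardized values at this bound (default 10);
#'   `NULL` disables clipping.
#' @return A list of class `"preprocess_config"`.
#' @export
preprocess_config <- function(target_sum = 1e4, log1p = TRUE, n_hvg = 3000,
                              scale = TRUE, clip = 10) {
  if (!is.null(target_sum) && target_sum <= 0) stop("target_sum must be > 0")
  if (n_hvg < 0) stop("n_hvg must be >= 0")
  structure(list(target_sum = target_sum, log1p = log1p,
                 n_hvg = as.integer(n_hvg), scale = scale, clip = clip),
            class = "preprocess_config")
}

#' Restrict two slices to their shared gene space
#'
#' The classifier trained on the source slice is applied to the target, so
#' both must present identical gene columns in identical order. Genes are
#' restricted to the intersection, ordered as in the source slice.
#'
#' @param source,target [st_slice] objects.
#' @return A list with elements `source` and `target`, both restricted to the
#'   common genes.
#' @export
align_genes <- function(source, target) {
  stopifnot(inherits(source, "st_slice"), inherits(target, "st_slice"))
  common <- intersect(source$gene_ids, target$gene_ids)
  if (length(common) == 0)
    stop("source and target share no genes; cannot align gene spaces")
  subset_genes <- function(s) {
    st_slice(s$expression[, common, drop = FALSE], s$coords,
             labels = s$labels, spot_ids = s$spot_ids, gene_ids = common,
             slice_id = s$slice_id)
  }
  list(source = subset_genes(source), target = subset_genes(target))
}

# Dispersion (variance / mean) of each column of a log-normalized matrix;
# genes with zero mean get dispersion 0. Ties broken by gene order.
gene_dispersion <- function(x) {
  mu <- colMeans(x)
  v <- apply(x, 2, stats::var)
  d <- ifelse(mu > 0, v / mu, 0)
  d[!is.finite(d)] <- 0
  d
}

#' Preprocess a slice's expression matrix
#'
#' Applies, in order: removal of all-zero spots (with a warning), total-count
#' normalization to `target_sum`, `log1p`, highly-variable-gene selection, and
#' per-gene standardization with clipping. Fully deterministic.
#'
#' When a `scaler` (per-gene means/sds) or `hvg` (gene-id set) computed on a
#' reference slice is supplied, those are applied instead of being re-fitted —
#' this is how a target slice is projected into the source slice's feature
#' space without leaking target statistics into gene choice.
#'
#' @param slice An [st_slice] with non-negative expression.
#' @param cfg A [preprocess_config].
#' @param hvg Optional character vector of gene ids to retain (overrides
#'   `cfg$n_hvg` ranking).
#' @param scaler Optional list with `mean` and `sd` per gene (named), reused
#'   for standardization.
#' @return An [st_slice] with transformed expression; the fitted gene set and
#'   scaler are attached as attributes `"hvg"` and `"scaler"` for reuse.
#' @export
preprocess_expression <- function(slice, cfg = preprocess_config(),
                                  hvg = NULL, scaler = NULL) {
  stopifnot(inherits(slice, "st_slice"))
  x <- slice$expression
  if (any(x < 0)) stop("expression must be non-negative before preprocessing")

  totals <- rowSums(x)
  keep <- totals > 0
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " all-zero spot(s): ",
            paste(utils::head(slice$spot_ids[!keep], 5), collapse = ", "))
    x <- x[keep, , drop = FALSE]
    totals <- totals[keep]
  }

  if (!is.null(cfg$target_sum))
    x <- x * (cfg$target_sum / totals)
  if (isTRUE(cfg$log1p))
    x <- log1p(x)

  if (is.null(hvg) && cfg$n_hvg > 0 && cfg$n_hvg < ncol(x)) {
    disp <- gene_dispersion(x)
    ord <- order(disp, decreasing = TRUE)  # stable: ties keep gene order
    hvg <- colnames(x)[sort(ord[seq_len(cfg$n_hvg)])]
  }
  if (!is.null(hvg)) {
    missing <- setdiff(hvg, colnames(x))
    if (length(missing))
      stop("hvg genes absent from slice: ", paste(utils::head(missing, 5), collapse = ", "))
    x <- x[, hvg, drop = FALSE]
  }

  if (isTRUE(cfg$scale)) {
    if (is.null(scaler)) {
      mu <- colMeans(x)
      sdv <- apply(x, 2, stats::sd)
      sdv[sdv == 0 | !is.finite(sdv)] <- 1
      scaler <- list(mean = mu, sd = sdv)
    } else {
      if (!all(colnames(x) %in% names(scaler$mean)))
        stop("scaler does not cover all genes of the slice")
      scaler <- list(mean = scaler$mean[colnames(x)],
                     sd = scaler$sd[colnames(x)])
    }
    x <- sweep(x, 2, scaler$mean, "-")
    x <- sweep(x, 2, scaler$sd, "/")
    if (!is.null(cfg$clip)) x <- pmin(pmax(x, -cfg$clip), cfg$clip)
  }

  # non-negativity is a raw-count invariant only; scaled values may be negative,
  # so validate shape/ids on a shifted copy and then restore the real matrix
  out <- st_slice(pmax(x, 0),
                  slice$coords[keep, , drop = FALSE],
                  labels = if (is.null(slice$labels)) NULL else slice$labels[keep],
                  spot_ids = slice$spot_ids[keep], gene_ids = colnames(x),
                  slice_id = slice$slice_id)
  out$expression <- x
  dimnames(out$expression) <- list(out$spot_ids, out$gene_ids)
  attr(out, "hvg") <- colnames(x)
  attr(out, "scaler") <- scaler
  out
}

#' Jointly preprocess a source/target pair
#'
#' Aligns gene spaces, fits the preprocessing (HVG ranking and per-gene
#' scaling statistics) on the source slice only, and applies the fitted
#' transform to the target. Fitting on the source avoids leaking the target
#' into gene selection and keeps genuine inter-slice shifts visible in the
#' target features, which is what the domain-adaptation phase consumes.
#'
#' @param source,target [st_slice] objects.
#' @param cfg A [preprocess_config].
#' @return List with preprocessed `source` and `target` slices.
#' @export
preprocess_pair <- function(source, target, cfg = preprocess_config()) {
  al <- align_genes(source, target)
  src <- preprocess_expression(al$source, cfg)
  tgt <- preprocess_expression(al$target, cfg,
                               hvg = attr(src, "hvg"),
                               scaler = attr(src, "scaler"))
  list(source = src, target = tgt)
}
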