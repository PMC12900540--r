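#' Training configuration
#'
#' Optimization schedule for the two phases: supervised source training
#' (encoder + classifier minimizing the cross-entropy loss, full batch) and
#' alternating adversarial adaptation (discriminator vs target encoder).
#' All randomness — parameter initialization, variational noise, walk
#' sampling — is driven by `seed`; identical configs give bit-identical runs.
#'
#' @param seed Integer seed.
#' @param source_epochs Maximum source-phase epochs (default 200), with early
#'   stop on a cross-entropy plateau (`patience`).
#' @param adapt_iters Maximum adversarial iterations (default 600), with early
#'   stop once the domain-classification accuracy has stayed inside
#'   `acc_band` for `band_hold` consecutive iterations.
#' @param d_steps,g_steps Discriminator / target-encoder updates per
#'   alternation (default 1 each).
#' @param lr_source Adam learning rate for the source phase (default 1e-3).
#' @param lr_d,lr_g Adam learning rates for the discriminator (default 3e-4)
#'   and target encoder (default 1e-4). The discriminator learns moderately
#'   faster than the generator; a slower generator keeps the encoder close to
#'   its source initialization, protecting the classifier's semantics. Rate
#'   pairs that let either player dominate (discriminator 10x faster, or both
#'   at 1e-3) either never reach the 0.5 equilibrium or destroy the
#'   embedding's class structure.
#' @param patience Source-phase early-stop patience in epochs (default 20).
#' @param acc_band Domain-accuracy convergence band (default
#'   `c(0.45, 0.55)`).
#' @param band_hold Iterations the accuracy must stay in the band (default
#'   50).
#' @param verbose Print progress.
#' @return A list of class `"train_config"`.
#' @export
train_config <- function(seed = 0, source_epochs = 200, adapt_iters = 600,
                         d_steps = 1, g_steps = 1, lr_source = 1e-3,
                         lr_d = 3e-4, lr_g = 1e-4, patience = 20,
                         acc_band = c(0.45, 0.55), band_hold = 50,
                         verbose = FALSE) {
  stopifnot(source_epochs >= 1, adapt_iters >= 1, d_steps >= 1, g_steps >= 1)
  structure(list(seed = as.integer(seed),
                 source_epochs = as.integer(source_epochs),
                 adapt_iters = as.integer(adapt_iters),
                 d_steps = as.integer(d_steps), g_steps = as.integer(g_steps),
                 lr_source = lr_source, lr_d = lr_d, lr_g = lr_g,
                 patience = as.integer(patience), acc_band = acc_band,
                 band_hold = as.integer(band_hold), verbose = verbose),
            class = "train_config")
}

branch_set <- function(graph_mode) {
  switch(graph_mode, both = c("A", "P"), knn = "A", ppmi = "P",
         stop("unknown graph_mode: ", graph_mode))
}

gmat_list <- function(graph, branches) {
  g <- list(A = graph$knn_norm, P = graph$ppmi_norm)
  g[branches]
}

#' Supervised source-phase training
#'
#' Jointly optimizes the dual-graph encoder and the cluster classifier on the
#' labeled source slice by minimizing the multiclass cross-entropy, full batch
#' with Adam. Variational noise is resampled every epoch (stochastic
#' regularization); batch-norm running statistics are accumulated here and
#' frozen afterwards.
#'
#' @param source Preprocessed, labeled [st_slice].
#' @param graph The source [spatial_graph].
#' @param enc_cfg An [encoder_config] (default: built from the slice's gene
#'   count).
#' @param cls_cfg A [classifier_config] (default: residual, 2 blocks).
#' @param tcfg A [train_config].
#' @param graph_mode `"both"`, `"knn"` or `"ppmi"` (single-graph ablations
#'   bypass attention fusion entirely).
#' @return A list of class `"source_state"`: trained `encoder` and
#'   `classifier` parameter trees, `bn_state`, configs, class names, training
#'   `history` (per-epoch loss and accuracy), and the deterministic source
#'   embeddings `h_source`.
#' @export
train_source <- function(source, graph, enc_cfg = NULL, cls_cfg = NULL,
                         tcfg = train_config(),
                         graph_mode = c("both", "knn", "ppmi")) {
  graph_mode <- match.arg(graph_mode)
  stopifnot(inherits(source, "st_slice"), inherits(graph, "spatial_graph"))
  if (is.null(source$labels)) stop("source slice must carry region labels")
  classes <- sort(unique(as.character(source$labels)))
  if (length(classes) < 2) stop("source labels contain fewer than 2 classes")

  X <- source$expression
  if (is.null(enc_cfg)) enc_cfg <- encoder_config(input_dim = ncol(X))
  if (enc_cfg$input_dim != ncol(X))
    stop("encoder input_dim (", enc_cfg$input_dim, ") != gene count (",
         ncol(X), ")")
  h_width <- 2L * enc_cfg$latent_dim
  if (is.null(cls_cfg)) cls_cfg <- classifier_config(length(classes), h_width)
  if (cls_cfg$width != h_width)
    stop("classifier width != encoder embedding width")

  branches <- branch_set(graph_mode)
  gmats <- gmat_list(graph, branches)
  Y <- one_hot(source$labels, classes)
  n <- nrow(X)

  with_seed(tcfg$seed, {
    enc <- init_encoder(enc_cfg, branches)
    cls <- init_classifier(cls_cfg)
    bn_state <- init_bn_state(cls_cfg)
    params <- list(enc = enc, cls = cls)
    opt <- adam_init(params)
    hist <- data.frame(epoch = integer(0), loss = numeric(0),
                       accuracy = numeric(0))
    best <- Inf
    wait <- 0L
    for (ep in seq_len(tcfg$source_epochs)) {
      eps <- lapply(gmats, function(g)
        matrix(stats::rnorm(n * enc_cfg$latent_dim), n, enc_cfg$latent_dim))
      fe <- encoder_forward(X, gmats, params$enc, eps = eps)
      fc <- classifier_forward(fe$h, params$cls, cls_cfg, bn_state, "train")
      bn_state <- fc$bn_state
      loss <- -mean(rowSums(Y * clamped_log(fc$probs, warn = FALSE)))
      if (!is.finite(loss))
        stop("non-finite classification loss at epoch ", ep,
             "; lower lr_source or check the input scaling")
      acc <- mean(max.col(fc$probs, ties.method = "first") ==
                    max.col(Y, ties.method = "first"))
      hist <- rbind(hist, data.frame(epoch = ep, loss = loss, accuracy = acc))
      dlogits <- (fc$probs - Y) / n
      cb <- classifier_backward(dlogits, fc, params$cls, cls_cfg)
      eg <- encoder_backward(cb$dh, fe, params$enc, gmats)
      st <- adam_step(params, list(enc = eg, cls = cb$grads), opt,
                      tcfg$lr_source)
      params <- st$params
      opt <- st$state
      if (loss < best - 1e-4) { best <- loss; wait <- 0L } else wait <- wait + 1L
      if (wait >= tcfg$patience) break
      if (tcfg$verbose && ep %% 25 == 0)
        message(sprintf("source epoch %d: loss %.4f acc %.3f", ep, loss, acc))
    }
    h_source <- encoder_forward(X, gmats, params$enc, eps = 0)$h
    rownames(h_source) <- source$spot_ids
    structure(list(encoder = params$enc, classifier = params$cls,
                   bn_state = bn_state, enc_cfg = enc_cfg, cls_cfg = cls_cfg,
                   classes = classes, branches = branches,
                   graph_mode = graph_mode, gene_ids = source$gene_ids,
                   history = hist, h_source = h_source),
              class = "source_state")
  })
}

#' Adversarial target-encoder adaptation
#'
#' Initializes the target encoder as a copy of the trained source encoder,
#' then alternates: `d_steps` discriminator updates minimizing the domain
#' binary cross-entropy on (frozen source embeddings, current target
#' embeddings), followed by `g_steps` target-encoder updates minimizing the
#' non-saturating generator loss with the discriminator frozen. The source
#' encoder and the cluster classifier are never touched. Both domains'
#' embeddings are drawn with fresh variational noise every step (when the
#' source slice is supplied), so the discriminator must separate the two
#' embedding distributions rather than memorize a fixed point set. Stops
#' early once, after a 100-iteration warm-up, the domain-classification
#' accuracy has stabilized near 0.5 (inside `tcfg$acc_band` for
#' `tcfg$band_hold` iterations); aborts if the generator loss exceeds 10x
#' its initial value.
#'
#' @param target Preprocessed target [st_slice] (same gene space as the
#'   source).
#' @param target_graph The target [spatial_graph].
#' @param source_state A trained `"source_state"` from [train_source].
#' @param disc_hidden Hidden widths of the domain discriminator (default
#'   `c(32, 16)`; deliberately small so it cannot memorize individual
#'   spots).
#' @param tcfg A [train_config].
#' @param source,source_graph The preprocessed source slice and its graph;
#'   when supplied, source embeddings are resampled through the frozen source
#'   encoder with fresh variational noise each step. Otherwise the fixed
#'   posterior-mean embeddings stored in `source_state` are used.
#' @return List with the adapted `encoder`, the `discriminator`, and a
#'   per-iteration `history` (`loss_d`, `loss_g`, `domain_accuracy`).
#' @export
adapt_target <- function(target, target_graph, source_state,
                         disc_hidden = c(32, 16), tcfg = train_config(),
                         source = NULL, source_graph = NULL) {
  stopifnot(inherits(source_state, "source_state"),
            inherits(target, "st_slice"),
            inherits(target_graph, "spatial_graph"))
  if (!identical(target$gene_ids, source_state$gene_ids))
    stop("target gene space differs from the one the source encoder was ",
         "trained on; run preprocess_pair/align_genes first")
  X <- target$expression
  gmats <- gmat_list(target_graph, source_state$branches)
  enc <- source_state$encoder           # copy-then-freeze initialization
  n_t <- nrow(X)
  ld_ <- source_state$enc_cfg$latent_dim
  branches <- source_state$branches
  sample_eps <- function(n) lapply(stats::setNames(branches, branches),
                                   function(b) matrix(stats::rnorm(n * ld_),
                                                      n, ld_))
  if (!is.null(source)) {
    Xs <- source$expression
    gmats_s <- gmat_list(source_graph, branches)
    draw_hs <- function() encoder_forward(Xs, gmats_s, source_state$encoder,
                                          eps = sample_eps(nrow(Xs)))$h
  } else {
    draw_hs <- function() source_state$h_source
  }
  with_seed(tcfg$seed + 1L, {
    disc <- init_discriminator(2L * ld_, disc_hidden)
    opt_d <- adam_init(disc)
    opt_g <- adam_init(enc)
    hist <- data.frame(iter = integer(0), loss_d = numeric(0),
                       loss_g = numeric(0), domain_accuracy = numeric(0))
    lg0 <- NA_real_
    in_band <- 0L
    warmup <- 100L  # band check arms only after the adversarial game settles
    for (it in seq_len(tcfg$adapt_iters)) {
      ld <- la <- NA_real_
      for (s in seq_len(tcfg$d_steps)) {
        ht <- encoder_forward(X, gmats, enc,
                              eps = if (is.null(source)) 0 else
                                sample_eps(n_t))$h
        fs <- disc_forward(draw_hs(), disc)
        ft <- disc_forward(ht, disc)
        ld <- -mean(clamped_log(fs$p, warn = FALSE)) -
          mean(clamped_log(1 - ft$p, warn = FALSE))
        la <- (mean(fs$p > 0.5) + mean(ft$p <= 0.5)) / 2
        # gate: a discriminator that is already winning sits this round out,
        # otherwise it out-paces the slower generator and no equilibrium forms
        if (la <= 0.6) {
          gs <- disc_backward(-(1 - fs$p) / length(fs$p), fs, disc)$grads
          gt <- disc_backward(ft$p / length(ft$p), ft, disc)$grads
          st <- adam_step(disc, map2_params(`+`, gs, gt), opt_d, tcfg$lr_d)
          disc <- st$params; opt_d <- st$state
        }
      }
      lg <- NA_real_
      for (s in seq_len(tcfg$g_steps)) {
        fe <- encoder_forward(X, gmats, enc,
                              eps = if (is.null(source)) 0 else
                                sample_eps(n_t))
        ft <- disc_forward(fe$h, disc)
        lg <- -mean(clamped_log(ft$p, warn = FALSE))
        # gate: an already-fooled discriminator gives no useful alignment
        # signal; pushing further only drags the embedding past the source
        if (la >= 0.45) {
          db <- disc_backward(-(1 - ft$p) / length(ft$p), ft, disc)
          eg <- encoder_backward(db$dh, fe, enc, gmats)
          st <- adam_step(enc, eg, opt_g, tcfg$lr_g)
          enc <- st$params; opt_g <- st$state
        }
      }
      if (is.na(lg0)) lg0 <- max(lg, log(2))  # floor at the equilibrium value
      if (!is.finite(lg) || lg > 10 * lg0)
        stop("adversarial divergence at iteration ", it,
             ": generator loss ", signif(lg, 4), " exceeded 10x its initial ",
             "value ", signif(lg0, 4), "; lower lr_g/lr_d")
      hist <- rbind(hist, data.frame(iter = it, loss_d = ld, loss_g = lg,
                                     domain_accuracy = la))
      in_band <- if (it > warmup && la >= tcfg$acc_band[1] &&
                     la <= tcfg$acc_band[2]) in_band + 1L else 0L
      if (in_band >= tcfg$band_hold) break
      if (tcfg$verbose && it %% 25 == 0)
        message(sprintf("adapt iter %d: L_D %.4f L_G %.4f acc %.3f",
                        it, ld, lg, la))
    }
    list(encoder = enc, discriminator = disc, history = hist)
  })
}

#' Predict region labels for a slice
#'
#' Deterministic forward pass (posterior mean, eval-mode batch norm) through
#' an encoder and the source-trained classifier. Labels carry the source
#' class names, so predictions are semantically transferable annotations.
#'
#' @param slice Preprocessed [st_slice] in the training gene space.
#' @param graph The slice's [spatial_graph].
#' @param source_state Trained `"source_state"` (supplies the classifier).
#' @param encoder_params Encoder parameter tree; defaults to the source
#'   encoder, pass the adapted target encoder for target slices.
#' @return List with `labels` (character), `probabilities` (`N x C`) and
#'   `embeddings` (`N x 2 * latent_dim`).
#' @export
predict_slice <- function(slice, graph, source_state,
                          encoder_params = source_state$encoder) {
  stopifnot(inherits(source_state, "source_state"))
  if (!identical(slice$gene_ids, source_state$gene_ids))
    stop("slice gene space differs from the training gene space")
  gmats <- gmat_list(graph, source_state$branches)
  h <- encoder_forward(slice$expression, gmats, encoder_params, eps = 0)$h
  probs <- classify(h, source_state$classifier, source_state$cls_cfg,
                    source_state$bn_state)
  colnames(probs) <- source_state$classes
  labels <- source_state$classes[max.col(probs, ties.method = "first")]
  rownames(probs) <- slice$spot_ids
  rownames(h) <- slice$spot_ids
  list(labels = labels, probabilities = probs, embeddings = h)
}

#' Fit a slice-to-slice transfer model
#'
#' The package's main entry point. Runs the full pipeline: gene-space
#' alignment and preprocessing (fitted on the source), construction of the
#' KNN and PPMI graphs per slice, supervised training of the dual-graph
#' encoder and residual classifier on the labeled source slice, optional
#' adversarial adaptation of a target encoder, and deterministic prediction
#' of the target's region labels. When the target slice carries held-out
#' labels, ARI/CA/confusion metrics are computed against them.
#'
#' @param source Labeled [st_slice] (the annotated reference).
#' @param target Unlabeled (or held-out-labeled) [st_slice].
#' @param k KNN neighbour count (default 6).
#' @param walk A [walk_config] for the PPMI graph.
#' @param preprocess A [preprocess_config].
#' @param graph_mode `"both"` (dual graph with attention fusion, default),
#'   `"knn"` or `"ppmi"` (single-graph ablations).
#' @param classifier_variant `"residual"` (default) or `"mlp"` (ablation).
#' @param n_blocks Classifier block count (default 2).
#' @param adapt Run the adversarial adaptation phase (default TRUE). With
#'   `FALSE`, the target is predicted through the source encoder directly.
#' @param encoder An [encoder_config]; default built from the preprocessed
#'   gene count.
#' @param disc_hidden Discriminator hidden widths.
#' @param train A [train_config] (seed, epochs, learning rates).
#' @return An object of class `"stransfer"`; see [print.stransfer],
#'   [summary.stransfer], [predict.stransfer], [plot.stransfer].
#' @export
#' @examples
#' pair <- generate_slice_pair(synthetic_config(n_spots = 120, n_genes = 24,
#'                                              markers_per_domain = 4))
#' fit <- stransfer(pair$source, pair$target,
#'                  train = train_config(source_epochs = 30, adapt_iters = 20))
#' fit
stransfer <- function(source, target, k = 6, walk = walk_config(),
                      preprocess = preprocess_config(),
                      graph_mode = c("both", "knn", "ppmi"),
                      classifier_variant = c("residual", "mlp"),
                      n_blocks = 2, adapt = TRUE, encoder = NULL,
                      disc_hidden = c(32, 16), train = train_config()) {
  graph_mode <- match.arg(graph_mode)
  classifier_variant <- match.arg(classifier_variant)
  cl <- match.call()
  t0 <- proc.time()[["elapsed"]]

  pp <- preprocess_pair(source, target, preprocess)
  src <- pp$source; tgt <- pp$target
  g_src <- spatial_graph(src, k = k, walk = walk)
  g_tgt <- spatial_graph(tgt, k = k, walk = walk)

  enc_cfg <- if (is.null(encoder))
    encoder_config(input_dim = ncol(src$expression)) else encoder
  cls_cfg <- classifier_config(length(unique(src$labels)),
                               width = 2L * enc_cfg$latent_dim,
                               n_blocks = n_blocks,
                               variant = classifier_variant)

  state <- train_source(src, g_src, enc_cfg, cls_cfg, train, graph_mode)

  adapt_out <- NULL
  target_encoder <- state$encoder
  if (isTRUE(adapt)) {
    adapt_out <- adapt_target(tgt, g_tgt, state, disc_hidden, train,
                              source = src, source_graph = g_src)
    target_encoder <- adapt_out$encoder
  }

  pred <- predict_slice(tgt, g_tgt, state, target_encoder)

  metrics <- NULL
  if (!is.null(tgt$labels))
    metrics <- confusion_report(tgt$labels, pred$labels)

  structure(list(
    predicted_labels = stats::setNames(pred$labels, tgt$spot_ids),
    probabilities = pred$probabilities,
    embeddings = list(source = state$h_source, target = pred$embeddings),
    history = list(source = state$history,
                   adapt = if (is.null(adapt_out)) NULL else adapt_out$history),
    metrics = metrics,
    source_state = state,
    target_encoder = target_encoder,
    discriminator = if (is.null(adapt_out)) NULL else adapt_out$discriminator,
    classes = state$classes,
    slices = list(source = src, target = tgt),
    graphs = list(source = g_src, target = g_tgt),
    config = list(k = k, walk = walk, preprocess = preprocess,
                  graph_mode = graph_mode,
                  classifier_variant = classifier_variant,
                  adapt = adapt, encoder = enc_cfg, classifier = cls_cfg,
                  disc_hidden = disc_hidden, train = train),
    elapsed = proc.time()[["elapsed"]] - t0,
    call = cl),
    class = "stransfer")
}

#' Balanced domain-classification accuracy of the fitted discriminator
#'
#' Evaluates the trained domain discriminator on held-out source and target
#' embeddings — equal numbers of each, so the accuracy is balanced. By
#' default the embeddings are fresh variational draws (not seen during
#' training), averaged over `samples` replicates; with `samples = 0` the
#' deterministic posterior-mean embeddings are used instead. Values near 0.5
#' indicate the target encoder has aligned the two domains; values near 1
#' mean the domains remain separable.
#'
#' @param object A fitted [stransfer] model with `adapt = TRUE`.
#' @param samples Number of held-out embedding draws to average over
#'   (default 10); 0 for posterior means.
#' @param seed Seed for the held-out draws (default: the training seed + 2).
#' @return Scalar accuracy in `[0, 1]`.
#' @export
domain_accuracy <- function(object, samples = 10, seed = NULL) {
  stopifnot(inherits(object, "stransfer"))
  if (is.null(object$discriminator))
    stop("model was fitted with adapt = FALSE; no discriminator available")
  disc <- object$discriminator
  bal_acc <- function(hs, ht)
    (mean(discriminate(hs, disc) > 0.5) +
       mean(discriminate(ht, disc) <= 0.5)) / 2
  if (samples == 0)
    return(bal_acc(object$embeddings$source, object$embeddings$target))
  st <- object$source_state
  br <- st$branches
  ld_ <- st$enc_cfg$latent_dim
  Xs <- object$slices$source$expression
  Xt <- object$slices$target$expression
  gs <- gmat_list(object$graphs$source, br)
  gt <- gmat_list(object$graphs$target, br)
  if (is.null(seed)) seed <- object$config$train$seed + 2L
  draw <- function(n) lapply(stats::setNames(br, br), function(b)
    matrix(stats::rnorm(n * ld_), n, ld_))
  with_seed(seed, {
    mean(vapply(seq_len(samples), function(i) {
      hs <- encoder_forward(Xs, gs, st$encoder, eps = draw(nrow(Xs)))$h
      ht <- encoder_forward(Xt, gt, object$target_encoder,
                            eps = draw(nrow(Xt)))$h
      bal_acc(hs, ht)
    }, numeric(1)))
  })
}

#' @export
print.stransfer <- function(x, ...) {
  cat("Slice-to-slice transfer model (stransfer)\n")
  cat("  source:", x$slices$source$slice_id, "-",
      nrow(x$slices$source$expression), "spots;",
      "target:", x$slices$target$slice_id, "-",
      nrow(x$slices$target$expression), "spots;",
      ncol(x$slices$source$expression), "genes\n")
  cat("  graph_mode:", x$config$graph_mode,
      "| classifier:", x$config$classifier_variant,
      "| adaptation:", if (x$config$adapt) "on" else "off", "\n")
  sh <- x$history$source
  cat(sprintf("  source phase: %d epochs, final loss %.4f, accuracy %.3f\n",
              nrow(sh), sh$loss[nrow(sh)], sh$accuracy[nrow(sh)]))
  if (!is.null(x$history$adapt)) {
    ah <- x$history$adapt
    cat(sprintf("  adaptation: %d iterations, final domain accuracy %.3f\n",
                nrow(ah), ah$domain_accuracy[nrow(ah)]))
  }
  if (!is.null(x$metrics))
    cat(sprintf("  target metrics: ARI %.3f, CA %.3f\n",
                x$metrics$ari, x$metrics$ca))
  invisible(x)
}

#' @rdname print.stransfer
#' @param object,x A fitted [stransfer] model.
#' @param ... Unused.
#' @export
summary.stransfer <- function(object, ...) {
  print(object)
  cat("\nPredicted label counts:\n")
  print(table(object$predicted_labels))
  if (!is.null(object$metrics)) {
    cat("\n")
    print(object$metrics)
  }
  invisible(object)
}

#' Predictions from a fitted transfer model
#'
#' With no new data, returns the target-slice predictions made at fit time.
#' With a new slice, preprocesses it with the transform fitted on the source
#' (same genes, same scaling), builds its spatial graphs with the fitted
#' `k`/walk settings, and predicts through the requested encoder.
#'
#' @param object A fitted [stransfer] model.
#' @param newdata Optional [st_slice] to annotate.
#' @param encoder Which encoder embeds `newdata`: the adapted `"target"`
#'   encoder (default) or the `"source"` encoder.
#' @param ... Unused.
#' @return A data frame with `spot_id`, `predicted_label` and per-class
#'   probability columns.
#' @export
predict.stransfer <- function(object, newdata = NULL,
                              encoder = c("target", "source"), ...) {
  encoder <- match.arg(encoder)
  if (is.null(newdata)) {
    pr <- object$probabilities
    return(data.frame(spot_id = rownames(pr),
                      predicted_label = unname(object$predicted_labels),
                      pr, check.names = FALSE, row.names = NULL))
  }
  stopifnot(inherits(newdata, "st_slice"))
  src_pp <- object$slices$source
  tgt <- preprocess_expression(newdata, object$config$preprocess,
                               hvg = attr(src_pp, "hvg"),
                               scaler = attr(src_pp, "scaler"))
  g <- spatial_graph(tgt, k = object$config$k, walk = object$config$walk)
  ep <- if (encoder == "target") object$target_encoder
        else object$source_state$encoder
  pred <- predict_slice(tgt, g, object$source_state, ep)
  data.frame(spot_id = tgt$spot_ids, predicted_label = pred$labels,
             pred$probabilities, check.names = FALSE, row.names = NULL)
}

#' Training-history diagnostics plot
#'
#' Base-graphics panels: source-phase cross-entropy and training accuracy,
#' and (when adaptation ran) the adversarial losses and the domain-
#' classification accuracy with its 0.5 equilibrium line.
#'
#' @param x A fitted [stransfer] model.
#' @param ... Unused.
#' @export
plot.stransfer <- function(x, ...) {
  has_adapt <- !is.null(x$history$adapt)
  op <- graphics::par(mfrow = c(if (has_adapt) 2 else 1, 2),
                      mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  sh <- x$history$source
  plot(sh$epoch, sh$loss, type = "l", xlab = "epoch", ylab = "cross-entropy",
       main = "source loss")
  plot(sh$epoch, sh$accuracy, type = "l", xlab = "epoch", ylab = "accuracy",
       main = "source accuracy", ylim = c(0, 1))
  if (has_adapt) {
    ah <- x$history$adapt
    graphics::matplot(ah$iter, cbind(ah$loss_d, ah$loss_g), type = "l",
                      lty = 1, col = c("black", "red"),
                      xlab = "iteration", ylab = "loss",
                      main = "adversarial losses")
    graphics::legend("topright", c("L_D", "L_G"), lty = 1,
                     col = c("black", "red"), bty = "n")
    plot(ah$iter, ah$domain_accuracy, type = "l", xlab = "iteration",
         ylab = "domain accuracy", main = "domain accuracy", ylim = c(0, 1))
    graphics::abline(h = 0.5, lty = 2)
  }
  invisible(x)
}

#' Write transfer results to disk
#'
#' Writes three artifacts into `out_dir`: `predictions.csv` (spot id,
#' predicted label, per-class probabilities), `embeddings_target.csv` and
#' `embeddings_source.csv` (fused embeddings), and `metrics.json` (evaluation
#' metrics when available, plus the configuration echo).
#'
#' @param result A fitted [stransfer] model.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the written file paths.
#' @export
write_result <- function(result, out_dir) {
  stopifnot(inherits(result, "stransfer"))
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  pred_path <- file.path(out_dir, "predictions.csv")
  utils::write.csv(predict(result), pred_path, row.names = FALSE, quote = FALSE)
  emb_t <- file.path(out_dir, "embeddings_target.csv")
  emb_s <- file.path(out_dir, "embeddings_source.csv")
  emb_df <- function(h) data.frame(spot_id = rownames(h), h,
                                   check.names = FALSE, row.names = NULL)
  utils::write.csv(emb_df(result$embeddings$target), emb_t,
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(emb_df(result$embeddings$source), emb_s,
                   row.names = FALSE, quote = FALSE)
  met_path <- file.path(out_dir, "metrics.json")
  cfg <- result$config
  met <- list(
    metrics = if (is.null(result$metrics)) NULL else
      list(ari = result$metrics$ari, ca = result$metrics$ca),
    config = list(k = cfg$k, walk_length = cfg$walk$walk_length,
                  walk_mode = cfg$walk$mode, graph_mode = cfg$graph_mode,
                  classifier_variant = cfg$classifier_variant,
                  adapt = cfg$adapt, seed = cfg$train$seed,
                  source_epochs = cfg$train$source_epochs,
                  adapt_iters = cfg$train$adapt_iters),
    classes = result$classes,
    elapsed_seconds = result$elapsed)
  jsonlite::write_json(met, met_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(pred_path, emb_t, emb_s, met_path))
}
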