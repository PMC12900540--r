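# Reduced-size configurations keep these runs to a few seconds each; the
# full-size study conditions are exercised in test-acceptance.R.

small_pair <- function(seed = 0, batch_shift = 1.0) {
  generate_slice_pair(synthetic_config(n_spots = 150, n_genes = 30,
                                       markers_per_domain = 4,
                                       batch_shift = batch_shift,
                                       seed = seed))
}
small_train <- function(seed = 0, ...) {
  train_config(seed = seed, source_epochs = 80, adapt_iters = 150,
               band_hold = 30, ...)
}

test_that("source training separates well-marked domains and converges", {
  pair <- small_pair()
  pp <- preprocess_pair(pair$source, pair$target)
  g <- spatial_graph(pp$source)
  st <- train_source(pp$source, g, tcfg = small_train())
  hist <- st$history
  expect_gte(hist$accuracy[nrow(hist)], 0.95)
  # 20-epoch moving average of the loss is non-increasing (up to the jitter
  # the per-epoch variational resampling leaves in a converged loss)
  ma <- stats::filter(hist$loss, rep(1 / 20, 20), sides = 1)
  ma <- ma[!is.na(ma)]
  expect_true(all(diff(ma) <= 1e-4))
})

test_that("identical seeds give identical source training runs", {
  pair <- small_pair()
  pp <- preprocess_pair(pair$source, pair$target)
  g <- spatial_graph(pp$source)
  s1 <- train_source(pp$source, g, tcfg = small_train())
  s2 <- train_source(pp$source, g, tcfg = small_train())
  expect_identical(s1$encoder, s2$encoder)
  expect_identical(s1$classifier, s2$classifier)
  expect_identical(s1$history, s2$history)
})

test_that("source training rejects degenerate label sets", {
  pair <- small_pair()
  pp <- preprocess_pair(pair$source, pair$target)
  g <- spatial_graph(pp$source)
  one_class <- pp$source
  one_class$labels <- rep("only", nrow(one_class$expression))
  expect_error(train_source(one_class, g, tcfg = small_train()), "2 classes")
  unlabeled <- pp$source
  unlabeled$labels <- NULL
  expect_error(train_source(unlabeled, g, tcfg = small_train()), "labels")
})

test_that("prediction is deterministic, normalized and self-consistent", {
  pair <- small_pair()
  pp <- preprocess_pair(pair$source, pair$target)
  g <- spatial_graph(pp$source)
  st <- train_source(pp$source, g, tcfg = small_train())
  pr1 <- predict_slice(pp$source, g, st)
  pr2 <- predict_slice(pp$source, g, st)
  expect_identical(pr1, pr2)
  expect_equal(unname(rowSums(pr1$probabilities)),
               rep(1, nrow(pp$source$expression)), tolerance = 1e-6)
  # eval-mode accuracy on the training slice reproduces train-time accuracy
  acc_eval <- mean(pr1$labels == pp$source$labels)
  acc_train <- st$history$accuracy[nrow(st$history)]
  expect_lt(abs(acc_eval - acc_train), 0.02)
})

test_that("prediction refuses a mismatched gene space", {
  pair <- small_pair()
  pp <- preprocess_pair(pair$source, pair$target)
  g <- spatial_graph(pp$source)
  st <- train_source(pp$source, g, tcfg = small_train())
  wrong <- pp$source
  wrong$gene_ids <- rev(wrong$gene_ids)
  expect_error(predict_slice(wrong, g, st), "gene space")
})

test_that("adaptation leaves the source encoder and classifier untouched", {
  pair <- small_pair()
  pp <- preprocess_pair(pair$source, pair$target)
  gs <- spatial_graph(pp$source)
  gt <- spatial_graph(pp$target)
  st <- train_source(pp$source, gs, tcfg = small_train())
  enc_before <- serialize(st$encoder, NULL)
  cls_before <- serialize(st$classifier, NULL)
  ad <- adapt_target(pp$target, gt, st, tcfg = small_train(),
                     source = pp$source, source_graph = gs)
  expect_identical(serialize(st$encoder, NULL), enc_before)
  expect_identical(serialize(st$classifier, NULL), cls_before)
  # but the target encoder did move
  expect_false(identical(ad$encoder, st$encoder))
  expect_identical(names(ad$history),
                   c("iter", "loss_d", "loss_g", "domain_accuracy"))
})

test_that("adaptation does no harm when there is no distribution shift", {
  pair <- small_pair(batch_shift = 0)
  fit_on <- stransfer(pair$source, pair$target, train = small_train())
  fit_off <- stransfer(pair$source, pair$target, adapt = FALSE,
                       train = small_train())
  expect_lt(abs(fit_on$metrics$ca - fit_off$metrics$ca), 0.05)
})

test_that("single-graph ablations drop the attention fuser", {
  pair <- small_pair()
  fit_knn <- stransfer(pair$source, pair$target, graph_mode = "knn",
                       adapt = FALSE, train = small_train())
  expect_null(fit_knn$source_state$encoder$att)
  expect_identical(fit_knn$source_state$branches, "A")
  fit_ppmi <- stransfer(pair$source, pair$target, graph_mode = "ppmi",
                        adapt = FALSE, train = small_train())
  expect_identical(fit_ppmi$source_state$branches, "P")
  expect_gt(fit_knn$metrics$ari, 0.3)
})

test_that("the fitted model prints, summarizes, predicts and writes results", {
  pair <- small_pair()
  fit <- stransfer(pair$source, pair$target, train = small_train())
  expect_s3_class(fit, "stransfer")
  expect_output(print(fit), "transfer model")
  expect_output(summary(fit), "Predicted label counts")

  pr <- predict(fit)
  expect_identical(nrow(pr), nrow(pair$target$expression))
  expect_equal(unname(rowSums(pr[, fit$classes])), rep(1, nrow(pr)),
               tolerance = 1e-6)

  # predicting a fresh slice through the fitted transform
  extra <- generate_slice_pair(synthetic_config(n_spots = 150, n_genes = 30,
                                                markers_per_domain = 4,
                                                seed = 77))$target
  pr2 <- predict(fit, newdata = extra)
  expect_identical(nrow(pr2), 150L)

  out <- tempfile()
  paths <- write_result(fit, out)
  expect_true(all(file.exists(paths)))
  back <- utils::read.csv(paths[1], check.names = FALSE)
  expect_identical(nrow(back), nrow(pair$target$expression))
  expect_identical(back$predicted_label, unname(fit$predicted_labels))
  expect_equal(unname(rowSums(back[, fit$classes])), rep(1, nrow(back)),
               tolerance = 1e-6)
  met <- jsonlite::read_json(paths[4])
  expect_equal(met$metrics$ari, fit$metrics$ari, tolerance = 1e-9)

  # training curves plot without error
  pdf(NULL)
  on.exit(dev.off(), add = TRUE)
  expect_silent(plot(fit))
})
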