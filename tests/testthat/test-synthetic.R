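test_that("strip layout makes contiguous, balanced, complete domains", {
  cfg <- synthetic_config()
  lay <- stransfer:::with_seed(1, generate_layout(cfg))
  counts <- table(lay$labels)
  expect_length(counts, 4)
  expect_true(all(abs(counts - 100) <= 5))
  # contiguity: every domain's y-range is disjoint from the others'
  rng <- vapply(paste0("R", 1:4),
                function(l) range(lay$coords[lay$labels == l, 2]),
                numeric(2))
  ord <- order(rng[1, ])
  expect_true(all(rng[2, ord][-4] <= rng[1, ord][-1]))
})

test_that("zero jitter reproduces an exact integer grid", {
  cfg <- synthetic_config(n_spots = 100, coordinate_jitter = 0)
  lay <- stransfer:::with_seed(2, generate_layout(cfg))
  expect_true(all(lay$coords == round(lay$coords)))
})

test_that("blob layout also covers every domain", {
  cfg <- synthetic_config(n_spots = 50, layout = "blobs", n_domains = 3,
                          markers_per_domain = 4)
  lay <- stransfer:::with_seed(3, generate_layout(cfg))
  expect_setequal(unique(lay$labels), paste0("R", 1:3))
})

test_that("expression carries no domain signal when the effect size is zero", {
  cfg <- synthetic_config(effect_size = 0)
  out <- stransfer:::with_seed(4, {
    lay <- generate_layout(cfg)
    x <- generate_expression(lay$labels, cfg)
    km <- stats::kmeans(log1p(x), centers = 4, nstart = 5)
    adjusted_rand_index(lay$labels, km$cluster)
  })
  expect_lt(abs(out), 0.05)
})

test_that("zero noise makes within-domain marker rows identical", {
  cfg <- synthetic_config(n_spots = 40, noise_sd = 0)
  out <- stransfer:::with_seed(5, {
    lay <- generate_layout(cfg)
    x <- generate_expression(lay$labels, cfg, round_counts = FALSE)
    list(lay = lay, x = x)
  })
  r1 <- out$x[out$lay$labels == "R1", 1:5, drop = FALSE]
  expect_true(all(apply(r1, 2, function(col) max(col) - min(col)) == 0))
})

test_that("marker fold change matches the generative law", {
  cfg <- synthetic_config(n_spots = 2000)
  out <- stransfer:::with_seed(6, {
    lay <- generate_layout(cfg)
    x <- generate_expression(lay$labels, cfg, round_counts = FALSE)
    list(lay = lay, x = x)
  })
  mk1 <- stransfer:::marker_sets(cfg)[[1]]
  member <- out$lay$labels == "R1"
  ratio <- colMeans(out$x[member, mk1]) / colMeans(out$x[!member, mk1])
  # mean log fold change across domain-1 markers approximates delta = 2
  expect_equal(mean(log(ratio)), 2, tolerance = 0.15)
})

test_that("batch effect is gene-wise multiplicative and vanishes at zero", {
  x <- matrix(rpois(200, 10) + 1, 20, 10)
  cfg0 <- synthetic_config(n_genes = 10, markers_per_domain = 2,
                           batch_shift = 0)
  expect_equal(stransfer:::with_seed(7, apply_batch_effect(x, cfg0)), x)
  cfgf <- synthetic_config(n_genes = 10, markers_per_domain = 2,
                           batch_frac = 0)
  expect_equal(stransfer:::with_seed(7, apply_batch_effect(x, cfgf)), x)

  cfg <- synthetic_config(n_genes = 10, markers_per_domain = 2)
  xb <- stransfer:::with_seed(8, apply_batch_effect(x, cfg))
  ratio <- xb / x
  per_gene_spread <- apply(ratio, 2, function(r) max(r) - min(r))
  expect_true(all(per_gene_spread < 1e-12))
  expect_equal(sum(abs(ratio[1, ] - 1) > 1e-12), 5)  # half the genes shifted
})

test_that("slice pairs share classes, are seeded, and differ by the batch shift", {
  p1 <- generate_slice_pair(synthetic_config(n_spots = 60, n_genes = 20,
                                             markers_per_domain = 4, seed = 9))
  p2 <- generate_slice_pair(synthetic_config(n_spots = 60, n_genes = 20,
                                             markers_per_domain = 4, seed = 9))
  expect_identical(p1$source$expression, p2$source$expression)
  expect_identical(p1$target$expression, p2$target$expression)
  expect_setequal(unique(p1$source$labels), unique(p1$target$labels))
  expect_true(isTRUE(attr(p1$target$labels, "held_out")))
})

test_that("stronger domain effects monotonically improve an oracle clustering", {
  mean_ari <- vapply(c(0, 1, 2), function(delta) {
    aris <- vapply(1:10, function(s) {
      cfg <- synthetic_config(n_spots = 200, effect_size = delta, seed = s)
      stransfer:::with_seed(s + 1000, {
        lay <- generate_layout(cfg)
        x <- generate_expression(lay$labels, cfg)
        km <- stats::kmeans(log1p(x), centers = 4, nstart = 3)
        adjusted_rand_index(lay$labels, km$cluster)
      })
    }, numeric(1))
    mean(aris)
  }, numeric(1))
  expect_true(all(diff(mean_ari) > 0))
})

test_that("without a batch shift the two slices are exchangeable in law", {
  cfg <- synthetic_config(batch_shift = 0, seed = 10)
  pair <- generate_slice_pair(cfg)
  # per-gene two-sample t tests on log expression: rejections at the nominal rate
  pvals <- vapply(seq_len(cfg$n_genes), function(j)
    stats::t.test(log1p(pair$source$expression[, j]),
                  log1p(pair$target$expression[, j]))$p.value, numeric(1))
  expect_lt(mean(pvals < 0.01), 0.1)
})

test_that("negative-binomial switch produces overdispersed counts", {
  cfg <- synthetic_config(n_spots = 100, count_model = "nb")
  x <- stransfer:::with_seed(11, {
    lay <- generate_layout(cfg)
    generate_expression(lay$labels, cfg)
  })
  expect_true(all(x == round(x)))
  expect_true(all(x >= 0))
})
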