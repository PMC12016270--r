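test_that("pearson_cor matches the closed form and flags degenerate input", {
  x <- c(1, 2, 3)
  expect_equal(pearson_cor(x, x), 1)
  expect_equal(pearson_cor(x, -x), -1)
  # closed form: cov 1.5, sd(x) = 1, sd(y) = sqrt(7/3)
  expect_equal(pearson_cor(x, c(1, 2, 4)), 1.5 / sqrt(7 / 3))
  expect_true(is.na(pearson_cor(c(1, 1, 1), x)))
  expect_true(is.na(pearson_cor(x, c(2, 2, 2))))
  expect_error(pearson_cor(1:2, 1:2))
  # scale/location invariance for a > 0
  withr::with_seed(8, {
    for (i in 1:5) {
      a <- runif(1, 0.1, 10); b <- rnorm(1)
      u <- rnorm(20); v <- rnorm(20)
      expect_equal(pearson_cor(a * u + b, v), pearson_cor(u, v))
    }
  })
})

test_that("pearson_delta correlates deltas, not raw profiles", {
  ctrl <- c(g1 = 1, g2 = 1, g3 = 1)
  true <- c(g1 = 2, g2 = 1, g3 = 0)
  pred <- c(g1 = 3, g2 = 1, g3 = -1)
  # proportional deltas [1,0,-1] vs [2,0,-2] correlate perfectly
  expect_equal(pearson_delta(pred, true, ctrl), 1)
  expect_equal(pearson_delta(true, true, ctrl), 1)
  # predicting the control (zero delta) is undefined, not zero
  expect_true(is.na(pearson_delta(ctrl, true, ctrl)))
  # invariance to adding any constant vector to both pred and true
  withr::with_seed(15, {
    shift <- rnorm(3)
    p2 <- rnorm(3); t2 <- rnorm(3)
    expect_equal(pearson_delta(p2 + shift, t2 + shift, ctrl + shift),
                 pearson_cor(p2 - ctrl, t2 - ctrl))
  })
})

test_that("pearson_delta_de restricts to the DE list", {
  genes <- sprintf("g%02d", 1:10)
  withr::with_seed(21, {
    ctrl <- setNames(rnorm(10), genes)
    true <- setNames(rnorm(10), genes)
    pred <- true
    pred[6:10] <- rnorm(5)  # scrambled outside the DE list
  })
  expect_equal(pearson_delta_de(pred, true, ctrl, genes[1:5]), 1)
  expect_equal(pearson_delta_de(pred, true, ctrl, genes),
               pearson_delta(pred, true, ctrl), tolerance = 1e-12)
  # restriction identity when the list is all genes
  expect_equal(pearson_delta_de(true, true, ctrl, genes), 1)
  expect_true(is.na(pearson_delta_de(pred, true, ctrl, genes[1:2])))
})

test_that("evaluate scores a perfect and a constant predictor correctly", {
  inst <- simulate_benchmark(small_sim(seed = 6))
  ds <- normalize_counts(inst$dataset)
  pb <- pseudobulk(ds)
  perts <- setdiff(rownames(pb), "ctrl")
  split <- make_split(perts, fractions = c(train = 0.5, validation = 0.2, test = 0.3),
                      seed = 6)
  perfect <- pb[split$test, , drop = FALSE]
  tm <- predict(fit_train_mean(pb[split$train, , drop = FALSE]), split$test)
  res <- evaluate(list(perfect = perfect, train_mean = tm), ds, split)
  per <- res$per_perturbation
  perfect_vals <- per$value[per$model == "perfect" & !is.na(per$value)]
  expect_equal(perfect_vals, rep(1, length(perfect_vals)))
  # identical predicted rows still yield distinct per-perturbation deltas
  tm_pd <- per$value[per$model == "train_mean" & per$metric == "pearson_delta"]
  expect_gt(length(unique(tm_pd)), 1L)
  agg <- res$aggregate
  expect_equal(agg$value[agg$model == "perfect" & agg$metric == "pearson_delta"],
               1, tolerance = 1e-12)
  expect_error(evaluate(list(bad = perfect[1, , drop = FALSE]), ds, split),
               "missing predictions")
})

test_that("evaluate matches an independent straight-line recomputation", {
  inst <- simulate_benchmark(small_sim(seed = 14))
  ds <- normalize_counts(inst$dataset)
  pb <- pseudobulk(ds)
  perts <- setdiff(rownames(pb), "ctrl")
  split <- make_split(perts, fractions = c(train = 0.5, validation = 0.2, test = 0.3),
                      seed = 14)
  tm <- predict(fit_train_mean(pb[split$train, , drop = FALSE]), split$test)
  res <- evaluate(list(train_mean = tm), ds, split, de_method = "ttest", k = 20)
  per <- res$per_perturbation
  ctrl <- pb["ctrl", ]
  for (p in split$test) {
    # straight-line oracle: plain cor() calls on explicit vectors
    expect_equal(per$value[per$perturbation == p & per$metric == "pearson"],
                 cor(tm[p, ], pb[p, ]), tolerance = 1e-12)
    expect_equal(per$value[per$perturbation == p & per$metric == "pearson_delta"],
                 cor(tm[p, ] - ctrl, pb[p, ] - ctrl), tolerance = 1e-12)
    top <- top_k_de(rank_genes(ds, p), 20)
    expect_equal(per$value[per$perturbation == p & per$metric == "pearson_delta_de"],
                 cor(tm[p, top] - ctrl[top], pb[p, top] - ctrl[top]),
                 tolerance = 1e-12)
    topnt <- top_k_de(rank_genes(ds, p), 20, exclude_targets = TRUE,
                      target_genes = ds$targets[[p]])
    expect_false(ds$targets[[p]] %in% topnt)
    expect_equal(per$value[per$perturbation == p &
                             per$metric == "pearson_delta_no_target"],
                 cor(tm[p, topnt] - ctrl[topnt], pb[p, topnt] - ctrl[topnt]),
                 tolerance = 1e-12)
  }
})

test_that("raw pearson is saturated while pearson_delta separates models", {
  # baseline expression magnitudes dominate raw-space correlation, so even
  # the constant train-mean prediction scores very high on raw pearson
  inst <- simulate_benchmark(small_sim(seed = 33, shared_fraction = 0.2))
  ds <- normalize_counts(inst$dataset)
  pb <- pseudobulk(ds)
  perts <- setdiff(rownames(pb), "ctrl")
  split <- make_split(perts, seed = 33)
  tm <- predict(fit_train_mean(pb[split$train, , drop = FALSE]), split$test)
  res <- evaluate(list(train_mean = tm), ds, split)
  agg <- res$aggregate
  expect_gt(agg$value[agg$metric == "pearson"], 0.9)
  expect_lt(agg$value[agg$metric == "pearson_delta"],
            agg$value[agg$metric == "pearson"] - 0.2)
})
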