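test_that("train mean predicts the column mean of training rows, always", {
  train <- rbind(p1 = c(1, 2), p2 = c(3, 4))
  colnames(train) <- c("gA", "gB")
  model <- fit_train_mean(train)
  pred <- predict(model, c("x", "y"))
  expect_equal(pred["x", ], c(gA = 2, gB = 3))
  expect_equal(pred["x", ], pred["y", ])
  one <- fit_train_mean(train[1, , drop = FALSE])
  expect_equal(predict(one, "z")["z", ], train[1, ])
  expect_error(fit_train_mean(train[0, , drop = FALSE]), "empty")
})

test_that("featurize is linear in combos and respects the rank bound", {
  withr::with_seed(41, {
    emb <- matrix(rnorm(50 * 8), 50, 8,
                  dimnames = list(sprintf("g%02d", 1:50), NULL))
  })
  labels <- c("g01", "g02", "g01+g02", "g03+g07")
  fm <- featurize(emb, labels)
  expect_equal(fm$n_components, 8L)  # d < 256: no padding
  expect_equal(fm$features["g01+g02", ],
               fm$features["g01", ] + fm$features["g02", ])
  # linearity holds for any pair via the transform helper
  f <- perturbation_features(fm, c("g05", "g09", "g05+g09"))
  expect_equal(f["g05+g09", ], f["g05", ] + f["g09", ])
  # missing genes: drop with warning, or error
  expect_warning(fm2 <- featurize(emb, c("g01", "nope")), "dropped")
  expect_equal(rownames(fm2$features), "g01")
  expect_error(featurize(emb, "nope", on_missing = "error"), "absent")
})

test_that("PCA reduction reconstructs a low-rank embedding exactly", {
  withr::with_seed(43, {
    basis <- matrix(rnorm(2 * 6), 2, 6)
    weights <- matrix(rnorm(30 * 2), 30, 2)
  })
  emb <- weights %*% basis  # rank 2 (up to centering)
  rownames(emb) <- sprintf("g%02d", 1:30)
  fm <- featurize(emb, rownames(emb), n_components = 6)
  recon <- fm$gene_scores[, 1:2] %*% t(fm$rotation[, 1:2])
  recon <- sweep(recon, 2L, fm$center, `+`)
  expect_equal(unname(recon), unname(emb), tolerance = 1e-10)
  # sign convention: largest-magnitude loading positive
  for (j in seq_len(ncol(fm$rotation))) {
    v <- fm$rotation[, j]
    expect_gt(v[which.max(abs(v))], 0)
  }
})

test_that("1-NN predicts the nearest training perturbation's profile", {
  withr::with_seed(45, {
    feats <- matrix(rnorm(6 * 4), 6, 4,
                    dimnames = list(paste0("p", 1:6), NULL))
    targets <- matrix(rnorm(6 * 10), 6, 10,
                      dimnames = list(paste0("p", 1:6),
                                      sprintf("g%02d", 1:10)))
    valf <- matrix(rnorm(2 * 4), 2, 4, dimnames = list(c("v1", "v2"), NULL))
    valt <- matrix(rnorm(2 * 10), 2, 10,
                   dimnames = list(c("v1", "v2"), colnames(targets)))
  })
  ctrl <- rep(0, 10)
  model <- fit_regressor(feats, targets, kind = "knn", grid = 1L,
                         val_features = valf, val_targets = valt,
                         control_row = ctrl)
  query <- feats["p3", , drop = FALSE] + 1e-6
  rownames(query) <- "q"
  expect_equal(predict(model, query)["q", ], targets["p3", ])
  expect_equal(colnames(predict(model, query)), colnames(targets))
  expect_error(fit_regressor(feats, targets, kind = "knn", grid = 10L,
                             val_features = valf, val_targets = valt,
                             control_row = ctrl), "k > training size")
  expect_error(fit_regressor(feats, targets, kind = "knn", grid = integer(),
                             val_features = valf, val_targets = valt,
                             control_row = ctrl), "empty")
})

test_that("ridge-limit elastic net gives equal coefficients on duplicated features", {
  withr::with_seed(47, {
    x <- rnorm(40)
    X <- cbind(f1 = x, f2 = x, f3 = rnorm(40))
    y <- cbind(g1 = 2 * x + rnorm(40, sd = 0.1),
               g2 = -x + rnorm(40, sd = 0.1),
               g3 = 0.5 * x + rnorm(40, sd = 0.1))
    rownames(X) <- paste0("p", 1:40)
    valX <- X[1:5, , drop = FALSE]; rownames(valX) <- paste0("v", 1:5)
    valY <- y[1:5, , drop = FALSE]; rownames(valY) <- rownames(valX)
  })
  model <- fit_regressor(X, y, kind = "en", grid = 0,
                         val_features = valX, val_targets = valY,
                         control_row = c(g1 = 0, g2 = 0, g3 = 0))
  beta <- as.matrix(glmnet::coef.glmnet(model$fit$glmnet,
                                        s = model$fit$lambda)$g1)
  # equality up to the coordinate-descent convergence tolerance
  expect_equal(beta["f1", 1], beta["f2", 1], tolerance = 1e-2)
  expect_gt(beta["f1", 1], 0)
})

test_that("random forest with one training point predicts that profile", {
  feats <- matrix(rnorm(4), 1, 4, dimnames = list("p1", NULL))
  targets <- matrix(1:5, 1, 5,
                    dimnames = list("p1", sprintf("g%02d", 1:5)))
  model <- fit_regressor(feats, targets, kind = "rf", grid = 1L,
                         val_features = feats, val_targets = targets,
                         control_row = rep(0, 5))
  q <- matrix(rnorm(4), 1, 4, dimnames = list("q", NULL))
  expect_equal(predict(model, q)["q", ], targets["p1", ])
})

test_that("hyperparameter choice is reproducible under a fixed seed", {
  inst <- simulate_benchmark(small_sim(seed = 17))
  ds <- normalize_counts(inst$dataset)
  pb <- pseudobulk(ds)
  perts <- setdiff(rownames(pb), "ctrl")
  split <- make_split(perts, fractions = c(train = 0.6, validation = 0.2, test = 0.2),
                      seed = 17)
  fm <- featurize(inst$embeddings, perts)
  fit_once <- function() {
    fit_regressor(fm$features[split$train, ], pb[split$train, ],
                  kind = "rf", grid = c(20L, 50L),
                  val_features = fm$features[split$validation, ],
                  val_targets = pb[split$validation, ],
                  control_row = pb["ctrl", ], seed = 99)
  }
  a <- fit_once(); b <- fit_once()
  expect_identical(a$hyperparameter, b$hyperparameter)
  expect_identical(a$validation_score, b$validation_score)
  q <- fm$features[split$test, , drop = FALSE]
  expect_identical(predict(a, q), predict(b, q))
})
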