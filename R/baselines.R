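#' Featurize perturbations from a gene-embedding table
#'
#' Fits a principal-component reduction on the full gene-embedding matrix
#' (all genes, not only perturbation targets) keeping at most `n_components`
#' components, then represents each perturbation by the reduced vector of
#' its target gene; combo perturbations get the elementwise sum of their
#' components' vectors. Component signs are fixed by forcing the
#' largest-magnitude loading of each component positive, so the reduction is
#' deterministic across platforms.
#'
#' @param emb Genes x d embedding matrix with gene rownames.
#' @param perturbations Perturbation labels (gene names, possibly joined by
#'   `combo_sep`).
#' @param n_components Maximum number of principal components. Default 256.
#' @param on_missing What to do when a label's gene is absent from `emb`:
#'   `"drop"` the perturbation with a warning (default) or `"error"`.
#' @param combo_sep Separator for combo labels.
#' @return A `feature_matrix`: list with `features` (perturbations x d'
#'   matrix), `gene_scores` (all genes' reduced vectors, so held-out
#'   perturbations are reproducible transforms), `rotation`, `center`,
#'   `n_components` (d' actually kept), `combo_sep`, and `dropped` (labels
#'   dropped for missing genes).
#' @export
featurize <- function(emb, perturbations, n_components = 256L,
                      on_missing = c("drop", "error"), combo_sep = "+") {
  on_missing <- match.arg(on_missing)
  stopifnot(is.matrix(emb), !is.null(rownames(emb)))
  pc <- stats::prcomp(emb, center = TRUE, scale. = FALSE)
  d <- min(n_components, ncol(pc$rotation))
  rotation <- pc$rotation[, seq_len(d), drop = FALSE]
  # sign convention: largest-magnitude loading of each component positive
  flip <- apply(rotation, 2L, function(v) sign(v[which.max(abs(v))]))
  rotation <- sweep(rotation, 2L, flip, `*`)
  scores <- sweep(emb, 2L, pc$center) %*% rotation
  fm <- structure(list(features = NULL, gene_scores = scores,
                       rotation = rotation, center = pc$center,
                       n_components = d, combo_sep = combo_sep,
                       dropped = character()),
                  class = "feature_matrix")
  fm$features <- perturbation_features(fm, perturbations, on_missing = on_missing)
  fm$dropped <- setdiff(perturbations, rownames(fm$features))
  fm
}

#' Reduced feature vectors for perturbation labels
#'
#' Looks up each label's target gene(s) in a fitted [featurize()] reduction;
#' combos get the elementwise sum of their components' reduced vectors.
#'
#' @param fm A `feature_matrix` from [featurize()].
#' @param labels Perturbation labels.
#' @param on_missing `"drop"` (with warning) or `"error"` for labels whose
#'   gene is absent from the embedding.
#' @return Labels x d' feature matrix (dropped labels omitted).
#' @export
perturbation_features <- function(fm, labels, on_missing = c("drop", "error")) {
  on_missing <- match.arg(on_missing)
  scores <- fm$gene_scores
  out <- matrix(NA_real_, length(labels), fm$n_components,
                dimnames = list(labels, colnames(fm$rotation)))
  keep <- logical(length(labels))
  for (i in seq_along(labels)) {
    parts <- strsplit(labels[i], fm$combo_sep, fixed = TRUE)[[1]]
    missing <- setdiff(parts, rownames(scores))
    if (length(missing)) {
      if (on_missing == "error") {
        stop("gene(s) absent from embedding: ", paste(missing, collapse = ", "))
      }
      next
    }
    out[i, ] <- colSums(scores[parts, , drop = FALSE])
    keep[i] <- TRUE
  }
  if (any(!keep)) {
    warning(sum(!keep), " perturbation(s) dropped (target gene absent from embedding): ",
            paste(labels[!keep], collapse = ", "))
  }
  out[keep, , drop = FALSE]
}

#' Train Mean baseline
#'
#' Stores the per-gene mean over the training perturbations' pseudo-bulk
#' profiles (control excluded by the caller) and predicts that single vector
#' for every test perturbation.
#'
#' @param train_pb Training perturbations x genes pseudo-bulk matrix.
#' @return A `baseline_model` of kind `"train_mean"`.
#' @export
fit_train_mean <- function(train_pb) {
  train_pb <- as.matrix(train_pb)
  if (nrow(train_pb) < 1L) stop("empty training set")
  structure(list(kind = "train_mean", mean_profile = colMeans(train_pb),
                 genes = colnames(train_pb), hyperparameter = NULL,
                 validation_score = NA_real_),
            class = "baseline_model")
}

#' Fit an embedding-feature regressor with validation-based tuning
#'
#' Multi-output regression of training pseudo-bulk profiles on perturbation
#' feature vectors, sweeping one hyperparameter and keeping the value with
#' the best mean validation Pearson Delta:
#' \describe{
#'   \item{rf}{random forest, one [ranger::ranger()] forest per output gene
#'     (the standard per-output multi-output strategy); tunes the tree
#'     count. The forest is grown once at the largest grid value and smaller
#'     values are evaluated on their first trees.}
#'   \item{en}{elastic net via [glmnet::glmnet()] with the multi-response
#'     Gaussian family; tunes the L1 ratio (glmnet's `alpha`), with the
#'     penalty strength `lambda` chosen on the validation set alongside it.}
#'   \item{knn}{k-nearest-neighbours: predicts the mean profile of the `k`
#'     nearest training perturbations in feature space; tunes `k`.}
#' }
#'
#' @param features Training perturbations x d' feature matrix (rows named;
#'   see [featurize()]).
#' @param targets Training perturbations x genes pseudo-bulk matrix, rows
#'   aligned with `features`.
#' @param kind `"rf"`, `"en"`, or `"knn"`.
#' @param val_features,val_targets Validation features and profiles
#'   (perturbations disjoint from training).
#' @param control_row Observed control profile, for the validation Pearson
#'   Delta.
#' @param grid Hyperparameter grid; defaults: rf trees
#'   `c(100, 200, 500)`, en L1 ratio `c(0.1, 0.5, 0.9)`, knn k
#'   `c(1, 3, 5, 10)` (k values above the training size are an error).
#' @param seed Integer seed for the stochastic fits.
#' @return A `baseline_model` with the fitted state, chosen hyperparameter
#'   and validation score.
#' @export
fit_regressor <- function(features, targets, kind = c("rf", "en", "knn"),
                          val_features, val_targets, control_row,
                          grid = NULL, seed = 1L) {
  kind <- match.arg(kind)
  features <- as.matrix(features); targets <- as.matrix(targets)
  val_features <- as.matrix(val_features); val_targets <- as.matrix(val_targets)
  stopifnot(nrow(features) == nrow(targets),
            nrow(val_features) == nrow(val_targets),
            ncol(val_features) == ncol(features))
  if (is.null(grid)) {
    grid <- switch(kind, rf = c(100L, 200L, 500L), en = c(0.1, 0.5, 0.9),
                   knn = c(1L, 3L, 5L, 10L))
    # the default knn grid adapts to small training sets; an explicit grid
    # with k beyond the training size is still an error
    if (kind == "knn") {
      grid <- grid[grid <= nrow(features)]
      if (length(grid) == 0L) grid <- 1L
    }
  }
  if (length(grid) == 0L) stop("empty hyperparameter grid")
  val_score <- function(pred) {
    mean(pearson_delta(pred, val_targets, control_row), na.rm = TRUE)
  }
  model <- switch(
    kind,
    rf = fit_rf(features, targets, grid, val_features, val_score, seed),
    en = fit_en(features, targets, grid, val_features, val_score),
    knn = fit_knn(features, targets, grid, val_features, val_score))
  model$kind <- kind
  model$genes <- colnames(targets)
  model$seed <- seed
  class(model) <- "baseline_model"
  model
}

fit_rf <- function(features, targets, grid, val_features, val_score, seed) {
  grid <- sort(as.integer(grid))
  if (nrow(features) == 1L) {
    # a forest grown on one sample predicts that sample everywhere
    return(list(fit = list(single_row = targets[1L, ]),
                hyperparameter = c(num_trees = grid[1L]),
                validation_score = NA_real_))
  }
  max_trees <- max(grid)
  forests <- lapply(seq_len(ncol(targets)), function(g) {
    ranger::ranger(x = features, y = targets[, g], num.trees = max_trees,
                   num.threads = 1L, seed = seed + g)
  })
  preds <- lapply(grid, function(nt) {
    p <- vapply(forests, function(f) {
      stats::predict(f, data = val_features, num.trees = nt,
                     num.threads = 1L)$predictions
    }, numeric(nrow(val_features)))
    matrix(p, nrow = nrow(val_features),
           dimnames = list(rownames(val_features), colnames(targets)))
  })
  scores <- vapply(preds, val_score, numeric(1L))
  best <- which.max(scores)
  list(fit = list(forests = forests, num_trees = grid[best]),
       hyperparameter = c(num_trees = grid[best]),
       validation_score = scores[best])
}

fit_en <- function(features, targets, grid, val_features, val_score) {
  best <- list(score = -Inf)
  for (alpha in grid) {
    fit <- glmnet::glmnet(features, targets, family = "mgaussian",
                          alpha = alpha)
    pred <- stats::predict(fit, newx = val_features)  # n x G x nlambda
    scores <- vapply(seq_len(dim(pred)[3L]),
                     function(j) val_score(pred[, , j, drop = TRUE]),
                     numeric(1L))
    j <- which.max(scores)
    if (scores[j] > best$score) {
      best <- list(fit = fit, alpha = alpha, lambda = fit$lambda[j],
                   score = scores[j])
    }
  }
  list(fit = list(glmnet = best$fit, lambda = best$lambda),
       hyperparameter = c(l1_ratio = best$alpha),
       validation_score = best$score)
}

fit_knn <- function(features, targets, grid, val_features, val_score) {
  grid <- sort(as.integer(grid))
  if (any(grid > nrow(features))) {
    stop("knn grid contains k > training size (", nrow(features), ")")
  }
  scores <- vapply(grid, function(k) {
    val_score(knn_predict(features, targets, val_features, k))
  }, numeric(1L))
  best <- which.max(scores)
  list(fit = list(train_features = features, train_targets = targets,
                  k = grid[best]),
       hyperparameter = c(k = grid[best]),
       validation_score = scores[best])
}

# mean profile of the k nearest training rows (Euclidean, deterministic
# ties by training row order)
knn_predict <- function(train_features, train_targets, new_features, k) {
  pred <- matrix(NA_real_, nrow(new_features), ncol(train_targets),
                 dimnames = list(rownames(new_features), colnames(train_targets)))
  for (i in seq_len(nrow(new_features))) {
    d2 <- colSums((t(train_features) - new_features[i, ])^2)
    nn <- order(d2)[seq_len(k)]
    pred[i, ] <- colMeans(train_targets[nn, , drop = FALSE])
  }
  pred
}

#' Predict post-perturbation pseudo-bulk profiles
#'
#' @param object A fitted `baseline_model`.
#' @param newdata For `train_mean`: a character vector of test perturbation
#'   labels. For `rf`/`en`/`knn`: a test perturbations x d' feature matrix
#'   with rownames (see [featurize()]).
#' @param ... Unused.
#' @return Test perturbations x genes matrix, gene order identical to the
#'   training targets.
#' @export
predict.baseline_model <- function(object, newdata, ...) {
  if (object$kind == "train_mean") {
    labels <- if (is.matrix(newdata)) rownames(newdata) else as.character(newdata)
    out <- matrix(rep(object$mean_profile, each = length(labels)),
                  nrow = length(labels),
                  dimnames = list(labels, object$genes))
    return(out)
  }
  newdata <- as.matrix(newdata)
  pred <- switch(
    object$kind,
    rf = {
      if (!is.null(object$fit$single_row)) {
        matrix(rep(object$fit$single_row, each = nrow(newdata)),
               nrow = nrow(newdata))
      } else {
        p <- vapply(object$fit$forests, function(f) {
          stats::predict(f, data = newdata, num.trees = object$fit$num_trees,
                         num.threads = 1L)$predictions
        }, numeric(nrow(newdata)))
        matrix(p, nrow = nrow(newdata))
      }
    },
    en = {
      p <- stats::predict(object$fit$glmnet, newx = newdata,
                          s = object$fit$lambda)
      matrix(p[, , 1L], nrow = nrow(newdata))
    },
    knn = knn_predict(object$fit$train_features, object$fit$train_targets,
                      newdata, object$fit$k))
  dimnames(pred) <- list(rownames(newdata), object$genes)
  pred
}

#' @export
print.baseline_model <- function(x, ...) {
  hp <- if (is.null(x$hyperparameter)) "none" else {
    paste(names(x$hyperparameter), x$hyperparameter, sep = "=", collapse = ", ")
  }
  cat(sprintf("baseline_model '%s': %d genes, hyperparameter %s, validation Pearson Delta %.3f\n",
              x$kind, length(x$genes), hp, x$validation_score))
  invisible(x)
}
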