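#' Pearson correlation with explicit handling of degenerate input
#'
#' Plain product-moment correlation, except that zero variance in either
#' vector yields `NA` (the correlation is undefined there) rather than an
#' error or a silent 0. The classic degenerate case is a predictor whose
#' predicted delta is constant.
#'
#' @param x,y Numeric vectors of equal length (at least 3).
#' @return Correlation in \[-1, 1\], or `NA_real_` when undefined.
#' @export
pearson_cor <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Pearson Delta: correlation of differential expression profiles
#'
#' Correlates predicted and observed profiles after subtracting the control
#' profile from both, i.e. in delta (differential expression) space. This
#' removes the dominant baseline-expression signal that makes raw-space
#' Pearson nearly uninformative for model comparison.
#'
#' @param pred Predicted post-perturbation profile: vector, or a
#'   perturbations x genes matrix (one correlation per row).
#' @param true Observed post-perturbation profile(s), same shape as `pred`.
#' @param control_row Observed control profile (vector over the same genes).
#' @return Scalar, or named vector when matrices are given; `NA` where the
#'   correlation is undefined.
#' @export
pearson_delta <- function(pred, true, control_row) {
  if (is.matrix(pred) || is.matrix(true)) {
    pred <- as.matrix(pred); true <- as.matrix(true)
    stopifnot(all(dim(pred) == dim(true)))
    out <- vapply(seq_len(nrow(pred)), function(i) {
      pearson_cor(pred[i, ] - control_row, true[i, ] - control_row)
    }, numeric(1L))
    names(out) <- rownames(pred)
    out
  } else {
    pearson_cor(pred - control_row, true - control_row)
  }
}

#' Pearson Delta restricted to a DE gene list
#'
#' [pearson_delta()] computed only on the named genes — typically the top-20
#' most differentially expressed genes of the perturbation, with or without
#' the CRISPR target gene(s).
#'
#' @param pred,true Profile vectors with gene names, or matrices with gene
#'   colnames.
#' @param control_row Observed control profile (named, same genes).
#' @param de_genes Character vector of gene names to restrict to (>= 3).
#' @return As [pearson_delta()]; `NA` when fewer than 3 usable genes.
#' @export
pearson_delta_de <- function(pred, true, control_row, de_genes) {
  gene_names <- if (is.matrix(pred)) colnames(pred) else names(pred)
  usable <- intersect(de_genes, gene_names)
  if (length(usable) < 3L) {
    return(if (is.matrix(pred)) rep(NA_real_, nrow(pred)) else NA_real_)
  }
  if (is.matrix(pred)) {
    pearson_delta(pred[, usable, drop = FALSE], true[, usable, drop = FALSE],
                  control_row[usable])
  } else {
    pearson_delta(pred[usable], true[usable], control_row[usable])
  }
}

#' Evaluate model predictions with the Pearson-delta metric family
#'
#' Scores each model's predicted test pseudo-bulk profiles against the
#' observed ones with four metrics per test perturbation:
#' \describe{
#'   \item{pearson}{raw-space correlation of predicted vs. observed profile;}
#'   \item{pearson_delta}{correlation of predicted vs. observed delta
#'     (profile minus observed control);}
#'   \item{pearson_delta_de}{pearson_delta restricted to the perturbation's
#'     top-`k` DE genes (computed from the observed cells);}
#'   \item{pearson_delta_no_target}{same, but the CRISPR target gene(s) are
#'     excluded from the top-`k` list and the list refilled to `k` — removing
#'     the trivially predictable target-gene signal.}
#' }
#' Aggregates are unweighted means over test perturbations; undefined
#' (`NA`) per-perturbation values are excluded from the mean and counted.
#'
#' @param predictions Named list: model name -> test perturbations x genes
#'   matrix of predicted post-perturbation pseudo-bulk profiles.
#' @param ds The log-normalized [perturb_dataset()] (source of observed
#'   profiles, DE rankings and target genes).
#' @param split A [make_split()] `split_spec`; predictions must cover all of
#'   `split$test`.
#' @param de_method DE ranking method, `"ttest"` or `"wilcoxon"`.
#' @param k Top-K DE list size. Default 20.
#' @return A `benchmark_result`: list with `per_perturbation` (long
#'   data.frame: model, perturbation, subgroup, metric, value), `aggregate`
#'   (model, metric, mean value, n_defined, n_undefined), and provenance
#'   fields `de_method`, `k`, `seed`.
#' @export
evaluate <- function(predictions, ds, split, de_method = c("ttest", "wilcoxon"),
                     k = 20L) {
  stopifnot(inherits(ds, "perturb_dataset"), inherits(split, "split_spec"),
            is.list(predictions), length(predictions) >= 1L)
  de_method <- match.arg(de_method)
  test_perts <- split$test
  for (mod in names(predictions)) {
    missing <- setdiff(test_perts, rownames(predictions[[mod]]))
    if (length(missing)) {
      stop("model '", mod, "' is missing predictions for: ",
           paste(missing, collapse = ", "))
    }
  }
  pb <- pseudobulk(ds)
  control_row <- pb[ds$control_label, ]
  # one DE ranking and top-K list pair per test perturbation, shared by all
  # models (the list comes from the observed data, not the predictions)
  de_lists <- lapply(test_perts, function(p) {
    ranking <- rank_genes(ds, p, method = de_method)
    list(top = top_k_de(ranking, k),
         top_no_target = top_k_de(ranking, k, exclude_targets = TRUE,
                                  target_genes = ds$targets[[p]]))
  })
  names(de_lists) <- test_perts
  rows <- list()
  for (mod in names(predictions)) {
    pred <- predictions[[mod]][test_perts, , drop = FALSE]
    for (p in test_perts) {
      truth <- pb[p, ]
      pr <- pred[p, ]
      vals <- c(
        pearson = pearson_cor(pr, truth),
        pearson_delta = pearson_delta(pr, truth, control_row),
        pearson_delta_de = pearson_delta_de(pr, truth, control_row,
                                            de_lists[[p]]$top),
        pearson_delta_no_target = pearson_delta_de(pr, truth, control_row,
                                                   de_lists[[p]]$top_no_target))
      rows[[length(rows) + 1L]] <- data.frame(
        model = mod, perturbation = p,
        subgroup = unname(split$subgroups[p]),
        metric = names(vals), value = unname(vals))
    }
  }
  per <- do.call(rbind, rows)
  rownames(per) <- NULL
  agg <- stats::aggregate(value ~ model + metric, data = per,
                          FUN = function(v) mean(v, na.rm = TRUE),
                          na.action = stats::na.pass)
  counts <- stats::aggregate(value ~ model + metric, data = per,
                             FUN = function(v) sum(!is.na(v)),
                             na.action = stats::na.pass)
  agg$n_defined <- counts$value
  agg$n_undefined <- length(test_perts) - agg$n_defined
  structure(list(per_perturbation = per, aggregate = agg,
                 de_method = de_method, k = k, seed = split$seed),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("benchmark_result: %d model(s), %d test perturbation(s), DE = %s, k = %d\n",
              length(unique(x$aggregate$model)),
              length(unique(x$per_perturbation$perturbation)),
              x$de_method, x$k))
  wide <- stats::reshape(x$aggregate[, c("model", "metric", "value")],
                         idvar = "model", timevar = "metric",
                         direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  print(wide, row.names = FALSE, digits = 3)
  invisible(x)
}
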