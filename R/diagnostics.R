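#' Pairwise correlations between delta profiles: dataset heterogeneity
#'
#' Computes the Pearson correlation between every pair of perturbation delta
#' profiles and summarises the dataset's heterogeneity by the median over the
#' strict upper triangle (each unordered pair counted once). A high median
#' means perturbations elicit similar transcriptional responses (low
#' heterogeneity); a low median means diverse responses.
#'
#' Rows with zero variance have undefined correlations; their pairs are
#' flagged `NA`, excluded from the median, and counted.
#'
#' @param deltas Perturbations x genes [delta_profiles()] matrix (at least 2
#'   rows and 3 genes).
#' @param train,test Optional label vectors; when given, the matrix rows are
#'   ordered train block first, then test, and the block boundary index is
#'   recorded (heatmap partitioning).
#' @return A `heterogeneity_report`: list with `cor_matrix` (P x P,
#'   symmetric, unit diagonal), `values` (upper-triangle correlations),
#'   `median_correlation`, `n_pairs`, `n_undefined`, and `train_test_boundary`
#'   (NULL unless `train`/`test` given).
#' @export
pairwise_delta_correlations <- function(deltas, train = NULL, test = NULL) {
  stopifnot(nrow(deltas) >= 2L, ncol(deltas) >= 3L)
  if (!is.null(train) || !is.null(test)) {
    ord <- c(intersect(train, rownames(deltas)), intersect(test, rownames(deltas)))
    ord <- c(ord, setdiff(rownames(deltas), ord))
    deltas <- deltas[ord, , drop = FALSE]
    boundary <- length(intersect(train, rownames(deltas)))
  } else {
    boundary <- NULL
  }
  sds <- apply(deltas, 1L, stats::sd)
  cm <- suppressWarnings(stats::cor(t(deltas)))
  cm[sds == 0, ] <- NA_real_
  cm[, sds == 0] <- NA_real_
  diag(cm) <- 1
  vals <- cm[upper.tri(cm)]
  structure(list(cor_matrix = cm, values = vals,
                 median_correlation = stats::median(vals, na.rm = TRUE),
                 n_pairs = length(vals), n_undefined = sum(is.na(vals)),
                 train_test_boundary = boundary),
            class = "heterogeneity_report")
}

#' @export
print.heterogeneity_report <- function(x, ...) {
  cat(sprintf(
    "heterogeneity_report: %d perturbations, %d pairs (%d undefined)\n  median pairwise delta correlation: %.3f\n",
    nrow(x$cor_matrix), x$n_pairs, x$n_undefined, x$median_correlation))
  invisible(x)
}

#' Benchmark dynamic range: best model minus Train Mean
#'
#' The aggregate Pearson Delta gap between the best non-baseline model and
#' the Train Mean baseline. A small (or negative) gap means the dataset
#' cannot discriminate between models.
#'
#' @param result A [evaluate()] `benchmark_result` containing `train_mean`
#'   and at least one other model.
#' @param baseline Name of the baseline model. Default `"train_mean"`.
#' @return Numeric gap (may be negative when the baseline wins), with the
#'   best model's name in the `"best_model"` attribute.
#' @export
dynamic_range <- function(result, baseline = "train_mean") {
  stopifnot(inherits(result, "benchmark_result"))
  agg <- result$aggregate
  pd <- agg[agg$metric == "pearson_delta", ]
  if (!baseline %in% pd$model) stop("baseline model '", baseline, "' absent from result")
  others <- pd[pd$model != baseline, ]
  if (nrow(others) == 0L) stop("need at least one non-baseline model")
  best <- others[which.max(others$value), ]
  gap <- best$value - pd$value[pd$model == baseline]
  attr(gap, "best_model") <- best$model
  gap
}

#' Relate dataset heterogeneity to benchmark dynamic range
#'
#' Pairs each dataset's median intra-dataset delta correlation with its
#' dynamic-range gap and reports the Spearman rank correlation between the
#' two — the diagnostic that diverse datasets (low median correlation) give
#' benchmarks more room to separate models.
#'
#' @param reports Named list of [pairwise_delta_correlations()] reports, one
#'   per dataset.
#' @param results Named list of [evaluate()] results, same names.
#' @return List with `table` (dataset, median_correlation, gap, best_model)
#'   and `spearman` (rank correlation between the two columns).
#' @export
heterogeneity_vs_range <- function(reports, results) {
  stopifnot(length(reports) >= 2L, length(reports) == length(results),
            identical(names(reports), names(results)))
  gaps <- vapply(results, dynamic_range, numeric(1L))
  best <- vapply(results, function(r) attr(dynamic_range(r), "best_model"),
                 character(1L))
  tab <- data.frame(
    dataset = names(reports),
    median_correlation = vapply(reports, `[[`, numeric(1L), "median_correlation"),
    gap = unname(gaps), best_model = unname(best))
  rownames(tab) <- NULL
  spearman <- suppressWarnings(
    stats::cor(tab$median_correlation, tab$gap, method = "spearman"))
  list(table = tab, spearman = spearman)
}
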