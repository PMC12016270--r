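#' Run the full post-perturbation prediction benchmark
#'
#' End-to-end pipeline: normalize (if raw) -> pseudo-bulk -> delta profiles
#' -> perturbation-exclusive split -> fit the requested baseline models ->
#' predict test profiles -> score with the Pearson-delta metric family ->
#' heterogeneity diagnostics. Either a dataset + embedding pair or a
#' [sim_config()] (from which both are generated) must be supplied.
#'
#' @param dataset A [perturb_dataset()] (raw counts or log-normalized), or
#'   `NULL` to simulate from `sim`.
#' @param embeddings Genes x d embedding matrix (required for `rf`/`en`/
#'   `knn`), or `NULL` to take the simulated embeddings.
#' @param sim Optional [sim_config()]; when given, `dataset`/`embeddings`
#'   default to a [simulate_benchmark()] draw from it.
#' @param models Subset of `c("train_mean", "rf", "en", "knn")`.
#' @param de_method `"ttest"` or `"wilcoxon"` for the top-K DE lists.
#' @param top_k DE list size (>= 3). Default 20.
#' @param fractions,seed Split fractions and seed (see [make_split()]); the
#'   seed also drives the stochastic model fits.
#' @param n_components Maximum PCA components for featurization.
#' @param grids Optional named list of hyperparameter grids overriding the
#'   [fit_regressor()] defaults, e.g. `list(rf = c(50, 100))`.
#' @param out_dir Optional directory; when given, writes `results.csv`
#'   (long per-perturbation metric table), `summary.json` (aggregates,
#'   provenance, diagnostics) and `heterogeneity.csv` (pairwise delta
#'   correlation matrix).
#' @return A `benchmark_run`: list with `result` ([evaluate()] output),
#'   `heterogeneity` ([pairwise_delta_correlations()] report), `gap`
#'   ([dynamic_range()], `NA` if only the baseline ran), `split`, `models`
#'   (fitted), `pseudobulk`, `deltas`, and `seed`.
#' @export
run_benchmark <- function(dataset = NULL, embeddings = NULL, sim = NULL,
                          models = c("train_mean", "rf", "en", "knn"),
                          de_method = c("ttest", "wilcoxon"), top_k = 20L,
                          fractions = c(train = 0.75, validation = 0.1, test = 0.15),
                          seed = 1L, n_components = 256L, grids = list(),
                          out_dir = NULL) {
  de_method <- match.arg(de_method)
  models <- match.arg(models, several.ok = TRUE)
  stopifnot(top_k >= 3L)
  if (is.null(dataset)) {
    if (is.null(sim)) stop("either a dataset or a sim_config is required")
    inst <- simulate_benchmark(sim)
    dataset <- inst$dataset
    if (is.null(embeddings)) embeddings <- inst$embeddings
  }
  if (!isTRUE(dataset$normalized)) dataset <- normalize_counts(dataset)
  needs_features <- any(models != "train_mean")
  if (needs_features && is.null(embeddings)) {
    stop("embedding table required for models: ",
         paste(setdiff(models, "train_mean"), collapse = ", "))
  }
  pb <- pseudobulk(dataset)
  deltas <- delta_profiles(pb, dataset$control_label)
  perts <- rownames(deltas)
  split <- make_split(perts, fractions = fractions, seed = seed,
                      combo_sep = dataset$combo_sep)
  control_row <- pb[dataset$control_label, ]
  train_pb <- pb[split$train, , drop = FALSE]
  val_pb <- pb[split$validation, , drop = FALSE]
  fitted <- list()
  predictions <- list()
  if (needs_features) {
    fm <- featurize(embeddings, perts, n_components = n_components,
                    combo_sep = dataset$combo_sep)
    feat <- function(labels) {
      missing <- setdiff(labels, rownames(fm$features))
      if (length(missing)) {
        stop("perturbation(s) not featurizable: ", paste(missing, collapse = ", "))
      }
      fm$features[labels, , drop = FALSE]
    }
  }
  for (mod in models) {
    if (mod == "train_mean") {
      fitted[[mod]] <- fit_train_mean(train_pb)
      predictions[[mod]] <- stats::predict(fitted[[mod]], split$test)
    } else {
      fitted[[mod]] <- fit_regressor(
        feat(split$train), train_pb, kind = mod,
        val_features = feat(split$validation), val_targets = val_pb,
        control_row = control_row, grid = grids[[mod]], seed = seed)
      predictions[[mod]] <- stats::predict(fitted[[mod]], feat(split$test))
    }
  }
  result <- evaluate(predictions, dataset, split, de_method = de_method,
                     k = top_k)
  het <- pairwise_delta_correlations(deltas, train = split$train,
                                     test = split$test)
  gap <- if (length(models) > 1L && "train_mean" %in% models) {
    dynamic_range(result)
  } else NA_real_
  run <- structure(list(result = result, heterogeneity = het, gap = gap,
                        split = split, models = fitted, pseudobulk = pb,
                        deltas = deltas, seed = seed),
                   class = "benchmark_run")
  if (!is.null(out_dir)) write_benchmark_run(run, out_dir)
  run
}

#' @export
print.benchmark_run <- function(x, ...) {
  print(x$result)
  cat(sprintf("median pairwise delta correlation: %.3f; dynamic range gap: %s\n",
              x$heterogeneity$median_correlation,
              if (is.na(x$gap)) "NA" else sprintf("%.3f (%s)", x$gap,
                                                  attr(x$gap, "best_model"))))
  invisible(x)
}

# results.csv + summary.json + heterogeneity.csv under out_dir
write_benchmark_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(run$result$per_perturbation,
                     file.path(out_dir, "results.csv"))
  cm <- run$heterogeneity$cor_matrix
  data.table::fwrite(data.table::data.table(perturbation = rownames(cm), cm),
                     file.path(out_dir, "heterogeneity.csv"))
  chosen <- lapply(run$models, function(m) as.list(m$hyperparameter))
  summary <- list(
    seed = run$seed,
    de_method = run$result$de_method,
    top_k = run$result$k,
    split = run$split[c("train", "validation", "test")],
    subgroups = as.list(run$split$subgroups),
    hyperparameters = chosen,
    aggregate = run$result$aggregate,
    median_pairwise_delta_correlation = run$heterogeneity$median_correlation,
    n_undefined_pairs = run$heterogeneity$n_undefined,
    dynamic_range_gap = if (is.na(run$gap)) NULL else as.numeric(run$gap),
    best_model = attr(run$gap, "best_model"))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Run the embedding-pathway coherence analysis with file I/O
#'
#' Thin orchestration over [coherence_test()]: accepts embedding matrices or
#' TSV paths and gene sets or a GMT path, and optionally writes the per-set
#' table (`coherence_sets.csv`) and summary (`coherence_summary.json`).
#'
#' @param embeddings A single embedding matrix or TSV path, or a named list
#'   of them (each tested on the common gene set, see
#'   [restrict_to_common_genes()]).
#' @param gene_sets Named list of gene sets or a GMT file path.
#' @param n_permutations,min_set_size,seed Passed to [coherence_test()].
#' @param out_dir Optional output directory.
#' @return A named list of `coherence_result` objects (one per embedding).
#' @export
run_coherence <- function(embeddings, gene_sets, n_permutations = 100L,
                          min_set_size = 2L, seed = 1L, out_dir = NULL) {
  if (is.character(gene_sets)) gene_sets <- read_gmt(gene_sets)
  load_emb <- function(e) if (is.character(e)) read_embedding_tsv(e) else e
  if (!is.list(embeddings)) embeddings <- list(embedding = embeddings)
  tables <- lapply(embeddings, load_emb)
  if (is.null(names(tables))) names(tables) <- paste0("embedding", seq_along(tables))
  tables <- restrict_to_common_genes(tables)
  results <- lapply(tables, coherence_test, gene_sets = gene_sets,
                    n_permutations = n_permutations,
                    min_set_size = min_set_size, seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    per_set <- do.call(rbind, lapply(names(results), function(nm) {
      cbind(embedding = nm, results[[nm]]$sets)
    }))
    data.table::fwrite(per_set, file.path(out_dir, "coherence_sets.csv"))
    summary <- lapply(results, function(r) {
      list(mean_delta = r$mean_delta, ci_low = r$ci[1L], ci_high = r$ci[2L],
           n_sets = nrow(r$sets), n_skipped = r$n_skipped,
           n_permutations = r$n_permutations, seed = r$seed)
    })
    jsonlite::write_json(summary, file.path(out_dir, "coherence_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  results
}
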