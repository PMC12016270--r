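#' Restrict embedding tables to their common gene set
#'
#' Keys every table by the intersection of all tables' gene identifiers so
#' that downstream comparisons use the identical gene universe.
#'
#' @param tables List of embedding matrices (gene rownames).
#' @return List of matrices restricted to the common genes (same order in
#'   each), with the intersection size in attribute `"n_common"`.
#' @export
restrict_to_common_genes <- function(tables) {
  stopifnot(is.list(tables), length(tables) >= 1L)
  common <- Reduce(intersect, lapply(tables, rownames))
  if (length(common) == 0L) stop("no genes common to all embedding tables")
  out <- lapply(tables, function(m) m[common, , drop = FALSE])
  attr(out, "n_common") <- length(common)
  out
}

#' Mean within-set pairwise embedding correlation
#'
#' Mean Pearson correlation over all unordered pairs of the set's member
#' genes' embedding vectors. Members absent from the embedding are ignored.
#'
#' @param emb Genes x d embedding matrix.
#' @param gene_set Character vector of member gene names.
#' @return Mean pairwise correlation, or `NA_real_` when fewer than 2
#'   members are present (set unusable).
#' @export
within_set_similarity <- function(emb, gene_set) {
  members <- intersect(gene_set, rownames(emb))
  if (length(members) < 2L) return(NA_real_)
  cm <- suppressWarnings(stats::cor(t(emb[members, , drop = FALSE])))
  mean(cm[upper.tri(cm)])
}

#' Sample a derangement (fixed-point-free permutation)
#'
#' Draws a uniform permutation of `keys` and redraws until it has no fixed
#' point, so no key keeps its own position. Rejection sampling from uniform
#' permutations; about e (~2.72) draws are needed on average regardless of
#' length.
#'
#' @param keys Character vector (length >= 2; a single key has no
#'   derangement).
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used (so repeated calls give independent draws).
#' @return Named character vector: `keys` -> the key whose position each one
#'   takes (guaranteed different from itself).
#' @export
derangement <- function(keys, seed = NULL) {
  n <- length(keys)
  if (n < 2L) stop("no derangement exists for fewer than 2 keys")
  draw <- function() {
    repeat {
      idx <- sample(n)
      if (!any(idx == seq_len(n))) return(idx)
    }
  }
  idx <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  stats::setNames(keys[idx], keys)
}

#' Embedding-pathway coherence test against a derangement null
#'
#' Asks whether an embedding places genes that share a pathway (gene set)
#' closer together than chance. For every usable set the observed mean
#' within-set pairwise correlation is compared with its mean under
#' `n_permutations` derangements of the gene-to-vector assignment — a
#' permutation null in which no gene keeps its own vector. Each permutation
#' draws one global derangement over the whole gene universe, applied to all
#' sets. The per-set difference (observed minus null mean) is the set's
#' delta; the collection-level summary is the mean delta across sets with a
#' 95% t-interval.
#'
#' @param emb Genes x d embedding matrix (d >= 3 for non-degenerate
#'   correlations; d = 2 is accepted with a warning).
#' @param gene_sets Named list of gene sets (e.g. from [read_gmt()]).
#' @param n_permutations Number of derangement draws. Default 100.
#' @param min_set_size Minimum member genes present for a set to be used
#'   (>= 2). Default 2.
#' @param seed Integer seed making the null draws reproducible.
#' @return A `coherence_result`: list with `sets` (data.frame: set,
#'   n_genes, observed, null_mean, delta), `mean_delta`, `ci` (95% interval),
#'   `n_permutations`, `n_skipped`, `seed`.
#' @export
coherence_test <- function(emb, gene_sets, n_permutations = 100L,
                           min_set_size = 2L, seed = 1L) {
  stopifnot(n_permutations >= 1L, min_set_size >= 2L)
  if (ncol(emb) < 3L) {
    warning("embedding dimension < 3: pairwise correlations are degenerate")
  }
  genes <- rownames(emb)
  present <- lapply(gene_sets, intersect, genes)
  usable <- lengths(present) >= min_set_size
  n_skipped <- sum(!usable)
  if (!any(usable)) stop("no usable gene sets (all below min_set_size)")
  sets <- present[usable]
  observed <- vapply(sets, within_set_similarity, numeric(1L), emb = emb)
  null_sum <- numeric(length(sets))
  withr::with_seed(seed, {
    for (b in seq_len(n_permutations)) {
      idx <- derangement(seq_along(genes))
      perm_emb <- emb[idx, , drop = FALSE]
      rownames(perm_emb) <- genes
      null_sum <- null_sum +
        vapply(sets, within_set_similarity, numeric(1L), emb = perm_emb)
    }
  })
  null_mean <- null_sum / n_permutations
  delta <- observed - null_mean
  mean_delta <- mean(delta)
  s <- length(delta)
  ci <- if (s > 1L) {
    half <- stats::qt(0.975, df = s - 1L) * stats::sd(delta) / sqrt(s)
    c(mean_delta - half, mean_delta + half)
  } else c(NA_real_, NA_real_)
  structure(list(
    sets = data.frame(set = names(sets), n_genes = lengths(sets),
                      observed = unname(observed), null_mean = unname(null_mean),
                      delta = unname(delta), row.names = NULL),
    mean_delta = mean_delta, ci = ci, n_permutations = n_permutations,
    n_skipped = n_skipped, seed = seed), class = "coherence_result")
}

#' @export
print.coherence_result <- function(x, ...) {
  cat(sprintf(
    "coherence_result: %d set(s) (%d skipped), %d permutations\n  mean delta %.4f, 95%% CI [%.4f, %.4f]\n",
    nrow(x$sets), x$n_skipped, x$n_permutations, x$mean_delta,
    x$ci[1L], x$ci[2L]))
  invisible(x)
}
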