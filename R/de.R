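#' Rank genes by differential expression between a perturbation and control
#'
#' Screens every gene with a two-sided two-sample test of the perturbed cells
#' against the control cells, on log-normalized expression, and orders genes
#' by ascending p-value, ties broken by descending absolute statistic, then
#' by gene name — a fully deterministic ranking key.
#'
#' `method = "ttest"` is the Welch (unequal-variance) t-test. Genes where
#' both groups have zero variance get statistic `+/-Inf` with p = 0 when the
#' group means differ, and statistic 0 with p = 1 when they are identical.
#'
#' `method = "wilcoxon"` is the Wilcoxon rank-sum (Mann-Whitney) test: exact
#' two-sided tail probabilities when both groups have at most 8 cells and the
#' gene has no tied values, otherwise the normal approximation with tie and
#' continuity correction.
#'
#' @param ds A log-normalized [perturb_dataset()].
#' @param perturbation Perturbation label to test.
#' @param control_label Control condition label; defaults to the dataset's.
#' @param method `"ttest"` (default) or `"wilcoxon"`.
#' @return A `de_ranking` data.frame with columns `gene`, `statistic`,
#'   `p_value`, `sign` (sign of the mean difference, perturbed minus
#'   control), ordered by the ranking key; the method is recorded in the
#'   `"method"` attribute.
#' @export
rank_genes <- function(ds, perturbation, control_label = ds$control_label,
                       method = c("ttest", "wilcoxon")) {
  stopifnot(inherits(ds, "perturb_dataset"))
  method <- match.arg(method)
  if (!isTRUE(ds$normalized)) {
    stop("rank_genes expects log-normalized data")
  }
  x <- ds$matrix[ds$conditions == perturbation, , drop = FALSE]
  y <- ds$matrix[ds$conditions == control_label, , drop = FALSE]
  if (nrow(x) < 2L || nrow(y) < 2L) {
    stop("need at least 2 cells in each group (got ", nrow(x), " perturbed, ",
         nrow(y), " control)")
  }
  res <- if (method == "ttest") welch_t_columns(x, y) else wilcoxon_columns(x, y)
  res$gene <- ds$gene_names
  res$sign <- sign(colMeans(x) - colMeans(y))
  ord <- order(res$p_value, -abs(res$statistic), res$gene)
  out <- res[ord, c("gene", "statistic", "p_value", "sign")]
  rownames(out) <- NULL
  attr(out, "method") <- method
  class(out) <- c("de_ranking", "data.frame")
  out
}

# column-wise Welch t-test; degenerate zero-variance columns follow the
# documented rule instead of propagating NaN
welch_t_columns <- function(x, y) {
  n1 <- nrow(x); n2 <- nrow(y)
  m1 <- colMeans(x); m2 <- colMeans(y)
  v1 <- colSums(sweep(x, 2L, m1)^2) / (n1 - 1L)
  v2 <- colSums(sweep(y, 2L, m2)^2) / (n2 - 1L)
  se2 <- v1 / n1 + v2 / n2
  stat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
  p <- 2 * stats::pt(-abs(stat), df)
  degen <- se2 == 0
  if (any(degen)) {
    diff <- (m1 - m2)[degen]
    stat[degen] <- ifelse(diff == 0, 0, sign(diff) * Inf)
    p[degen] <- ifelse(diff == 0, 1, 0)
  }
  data.frame(statistic = stat, p_value = p)
}

# column-wise Wilcoxon rank-sum; exact via the null U distribution (pwilcox)
# for small untied groups, else normal approximation with tie correction
wilcoxon_columns <- function(x, y, exact_max_n = 8L) {
  n1 <- nrow(x); n2 <- nrow(y)
  G <- ncol(x)
  stat <- numeric(G); p <- numeric(G)
  allow_exact <- n1 <= exact_max_n && n2 <= exact_max_n
  for (g in seq_len(G)) {
    v <- c(x[, g], y[, g])
    r <- rank(v)
    ties <- table(r)
    has_ties <- any(ties > 1L)
    u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2  # Mann-Whitney U for group 1
    stat[g] <- u
    if (allow_exact && !has_ties) {
      p_lo <- stats::pwilcox(u, n1, n2)
      p_hi <- stats::pwilcox(u - 1, n1, n2, lower.tail = FALSE)
      p[g] <- min(1, 2 * min(p_lo, p_hi))
    } else {
      mu <- n1 * n2 / 2
      tie_term <- sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1))
      sigma2 <- n1 * n2 / 12 * (n1 + n2 + 1 - tie_term)
      if (sigma2 == 0) { # all values tied: no evidence either way
        p[g] <- 1
        stat[g] <- mu
        next
      }
      z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
      p[g] <- min(1, 2 * stats::pnorm(-abs(z)))
    }
  }
  data.frame(statistic = stat, p_value = p)
}

#' Select the top-K differentially expressed genes
#'
#' Takes the first `k` genes of a [rank_genes()] ranking. With
#' `exclude_targets = TRUE` the perturbation's CRISPR target gene(s) are
#' removed from the ranking first and the list is refilled to `k` from the
#' remaining genes, so the returned list keeps length `k` whenever enough
#' genes exist.
#'
#' @param ranking A `de_ranking` from [rank_genes()].
#' @param k Number of genes to return (default 20).
#' @param exclude_targets Remove `target_genes` before selecting?
#' @param target_genes Character vector of CRISPR target gene names.
#' @return Character vector of at most `k` gene names; shorter with a warning
#'   when fewer are available.
#' @export
top_k_de <- function(ranking, k = 20L, exclude_targets = FALSE,
                     target_genes = character()) {
  stopifnot(k >= 1L)
  genes <- ranking$gene
  if (exclude_targets) genes <- setdiff(genes, target_genes)
  if (k > length(genes)) {
    warning("requested top ", k, " genes but only ", length(genes),
            " available; returning all")
    k <- length(genes)
  }
  genes[seq_len(k)]
}
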