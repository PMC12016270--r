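#' Configuration for the synthetic Perturb-seq generator
#'
#' The generator draws per-perturbation true delta profiles from a shared /
#' private Gaussian mixture whose mixing weight `shared_fraction` directly
#' sets the expected pairwise Pearson correlation between delta profiles —
#' the knob that controls dataset heterogeneity. Real benchmark screens span
#' median pairwise correlations from roughly 0.1 (genome-wide CRISPRi) to
#' 0.66 (pathway-focused screens), so `shared_fraction` covers that range;
#' the default 0.4 sits mid-range.
#'
#' Perturbation labels are their target gene's name; combos join two singles
#' with `"+"`. Each single perturbation belongs to one of `n_pathways`
#' simulated pathways; perturbations in the same pathway share part of their
#' private response (weight `pathway_cohesion`), which is what makes
#' pathway-structured embeddings informative about response similarity.
#'
#' @param n_genes Number of genes G.
#' @param n_perturbations Number of single perturbations P.
#' @param n_combos Number of dual ("A+B") perturbations built from random
#'   pairs of singles.
#' @param cells_per_condition Cells simulated per perturbation.
#' @param control_cells Cells simulated for the control condition.
#' @param shared_fraction Mixing weight rho in \[0,1\]; expected pairwise
#'   delta correlation between perturbations in different pathways.
#' @param pathway_cohesion Fraction of the private component shared within a
#'   pathway; same-pathway pairs have expected correlation
#'   `rho + (1-rho)*pathway_cohesion`.
#' @param delta_scale Standard deviation of true per-gene log-space effects.
#' @param target_effect Signed log-space shift applied to each perturbation's
#'   own target gene: negative mimics CRISPRi knockdown, positive CRISPRa
#'   activation.
#' @param target_mode `"overwrite"` (default; the target entry is set to
#'   `target_effect`, clean knockdown semantics) or `"add"`.
#' @param count_depth Expected total reads per cell.
#' @param nb_dispersion Negative-binomial overdispersion (1/size); 0 gives
#'   Poisson counts (default).
#' @param baseline_log_sd SD of per-gene baseline log-expression, creating
#'   the orders-of-magnitude expression spread typical of scRNA-seq.
#' @param n_pathways Number of simulated pathways.
#' @param embedding_dim Dimension of simulated gene-embedding vectors.
#' @param embedding_noise SD of the noise added to the pathway centroid for
#'   target genes (0 = noise-free pathway embeddings).
#' @param seed Integer seed; all generator functions are deterministic given
#'   the configuration.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 2000, n_perturbations = 100, n_combos = 0,
                       cells_per_condition = 50, control_cells = 500,
                       shared_fraction = 0.4, pathway_cohesion = 0.5,
                       delta_scale = 0.5, target_effect = -2,
                       target_mode = c("overwrite", "add"),
                       count_depth = 5000, nb_dispersion = 0,
                       baseline_log_sd = 2,
                       n_pathways = 10, embedding_dim = 32,
                       embedding_noise = 0.1, seed = 1L) {
  target_mode <- match.arg(target_mode)
  cfg <- list(n_genes = as.integer(n_genes),
              n_perturbations = as.integer(n_perturbations),
              n_combos = as.integer(n_combos),
              cells_per_condition = as.integer(cells_per_condition),
              control_cells = as.integer(control_cells),
              shared_fraction = shared_fraction,
              pathway_cohesion = pathway_cohesion,
              delta_scale = delta_scale, target_effect = target_effect,
              target_mode = target_mode, count_depth = count_depth,
              nb_dispersion = nb_dispersion,
              baseline_log_sd = baseline_log_sd,
              n_pathways = as.integer(n_pathways),
              embedding_dim = as.integer(embedding_dim),
              embedding_noise = embedding_noise, seed = as.integer(seed))
  stopifnot(cfg$n_genes >= 1L, cfg$n_perturbations >= 1L,
            cfg$cells_per_condition >= 1L, cfg$control_cells >= 1L,
            cfg$shared_fraction >= 0, cfg$shared_fraction <= 1,
            cfg$pathway_cohesion >= 0, cfg$pathway_cohesion <= 1,
            cfg$count_depth > 0, cfg$nb_dispersion >= 0,
            cfg$n_combos >= 0L,
            cfg$n_perturbations <= cfg$n_genes)
  if (cfg$n_combos > 0L && cfg$n_perturbations < 2L) {
    stop("combos require at least 2 single perturbations")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate ground-truth delta profiles
#'
#' Draws the true log-space delta profile of each perturbation as
#' `delta_scale * (sqrt(rho) * s + sqrt(1-rho) * u_p)` per gene, where `s` is
#' one standard-normal gene vector shared by all perturbations and `u_p` is
#' private; `u_p` itself mixes a pathway-level vector (weight
#' `pathway_cohesion`) with a perturbation-specific one, so the expected
#' pairwise correlation is `rho` across pathways and
#' `rho + (1-rho)*pathway_cohesion` within. The perturbation's own target
#' gene is then set (or shifted, see `target_mode`) to `target_effect`.
#' Combos are the sum of their components' deltas plus a combo-specific
#' private vector, with both target entries re-applied.
#'
#' @param cfg A [sim_config()].
#' @return A `ground_truth` list: `deltas` (perturbations x genes matrix,
#'   rownames the labels), `pathways` (named integer vector, pathway of each
#'   single perturbation), `targets` (named list label -> target genes),
#'   `gene_names`, and `config`.
#' @export
simulate_deltas <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  G <- cfg$n_genes; P <- cfg$n_perturbations
  gene_names <- sprintf("g%04d", seq_len(G))
  rho <- cfg$shared_fraction; tau <- cfg$pathway_cohesion
  withr::with_seed(cfg$seed, {
    target_idx <- sample(G, P)
    labels <- gene_names[target_idx]
    pathways <- sample(cfg$n_pathways, P, replace = TRUE)
    names(pathways) <- labels
    s <- rnorm(G)
    w <- matrix(rnorm(cfg$n_pathways * G), cfg$n_pathways, G)
    shared <- sqrt(rho) * s
    deltas <- matrix(0, P, G, dimnames = list(labels, gene_names))
    for (p in seq_len(P)) {
      u <- sqrt(tau) * w[pathways[p], ] + sqrt(1 - tau) * rnorm(G)
      deltas[p, ] <- cfg$delta_scale * (shared + sqrt(1 - rho) * u)
    }
    targets <- as.list(labels)
    names(targets) <- labels
    apply_target <- function(row, tgt_idx) {
      if (cfg$target_mode == "overwrite") row[tgt_idx] <- cfg$target_effect
      else row[tgt_idx] <- row[tgt_idx] + cfg$target_effect
      row
    }
    for (p in seq_len(P)) deltas[p, ] <- apply_target(deltas[p, ], target_idx[p])
    if (cfg$n_combos > 0L) {
      pairs <- matrix(nrow = 0L, ncol = 2L)
      # distinct unordered pairs of singles
      all_pairs <- t(combn(P, 2L))
      pairs <- all_pairs[sample(nrow(all_pairs), min(cfg$n_combos, nrow(all_pairs))), ,
                         drop = FALSE]
      combo_rows <- matrix(0, nrow(pairs), G)
      combo_labels <- character(nrow(pairs))
      for (i in seq_len(nrow(pairs))) {
        a <- pairs[i, 1L]; b <- pairs[i, 2L]
        combo_labels[i] <- paste(labels[a], labels[b], sep = "+")
        row <- deltas[a, ] + deltas[b, ] +
          cfg$delta_scale * sqrt(1 - rho) * sqrt(1 - tau) * rnorm(G)
        row <- apply_target(row, target_idx[a])
        row <- apply_target(row, target_idx[b])
        combo_rows[i, ] <- row
        targets[[combo_labels[i]]] <- c(labels[a], labels[b])
      }
      rownames(combo_rows) <- combo_labels
      colnames(combo_rows) <- gene_names
      deltas <- rbind(deltas, combo_rows)
    }
  })
  structure(list(deltas = deltas, pathways = pathways, targets = targets,
                 gene_names = gene_names, config = cfg),
            class = "ground_truth")
}

#' Simulate single-cell counts from ground-truth deltas
#'
#' For each condition, per-cell counts are drawn with expected proportions
#' proportional to `exp(mu_g + delta_g)`, where `mu_g` is a per-gene baseline
#' log-expression drawn once from `N(0, baseline_log_sd^2)` (giving the
#' realistic spread of expression magnitudes) and `delta` is the condition's
#' true effect (zero for control). Counts are Poisson with mean
#' `count_depth * proportion`, or negative binomial when `nb_dispersion > 0`.
#'
#' @param cfg A [sim_config()].
#' @param truth A [simulate_deltas()] result matching `cfg`.
#' @return A raw-count [perturb_dataset()] with the baseline `mu` attached as
#'   attribute `"baseline_mu"`.
#' @export
simulate_cells <- function(cfg, truth) {
  stopifnot(inherits(cfg, "sim_config"), inherits(truth, "ground_truth"))
  G <- cfg$n_genes
  labels <- rownames(truth$deltas)
  n_cond <- length(labels) + 1L
  counts_list <- vector("list", n_cond)
  conds_list <- vector("list", n_cond)
  withr::with_seed(cfg$seed + 1L, {
    mu <- rnorm(G, sd = cfg$baseline_log_sd)
    draw <- function(delta, n_cells) {
      lam <- exp(mu + delta)
      prop <- lam / sum(lam)
      mean_mat <- matrix(cfg$count_depth * prop, n_cells, G, byrow = TRUE)
      if (cfg$nb_dispersion > 0) {
        matrix(rnbinom(n_cells * G, mu = mean_mat, size = 1 / cfg$nb_dispersion),
               n_cells, G)
      } else {
        matrix(rpois(n_cells * G, mean_mat), n_cells, G)
      }
    }
    counts_list[[1L]] <- draw(rep(0, G), cfg$control_cells)
    conds_list[[1L]] <- rep("ctrl", cfg$control_cells)
    for (i in seq_along(labels)) {
      counts_list[[i + 1L]] <- draw(truth$deltas[i, ], cfg$cells_per_condition)
      conds_list[[i + 1L]] <- rep(labels[i], cfg$cells_per_condition)
    }
  })
  m <- do.call(rbind, counts_list)
  colnames(m) <- truth$gene_names
  ds <- perturb_dataset(m, unlist(conds_list), truth$gene_names,
                        control_label = "ctrl", normalized = FALSE)
  attr(ds, "baseline_mu") <- mu
  ds
}

#' Simulate gene embeddings matched to the ground truth
#'
#' Target genes of perturbations in the same simulated pathway receive
#' vectors near a shared pathway centroid (centroid + `embedding_noise`
#' Gaussian noise); all other genes receive independent standard-normal
#' vectors. With small noise the embedding similarity structure mirrors the
#' pathway structure of the responses, which is what makes it an informative
#' perturbation featurization.
#'
#' @param cfg A [sim_config()].
#' @param truth A [simulate_deltas()] result matching `cfg`.
#' @return Genes x `embedding_dim` numeric matrix with gene rownames.
#' @export
simulate_embeddings <- function(cfg, truth) {
  stopifnot(inherits(cfg, "sim_config"), inherits(truth, "ground_truth"))
  G <- cfg$n_genes; d <- cfg$embedding_dim
  withr::with_seed(cfg$seed + 2L, {
    emb <- matrix(rnorm(G * d), G, d, dimnames = list(truth$gene_names, NULL))
    centroids <- matrix(rnorm(cfg$n_pathways * d), cfg$n_pathways, d)
    for (lab in names(truth$pathways)) {
      emb[lab, ] <- centroids[truth$pathways[lab], ] +
        cfg$embedding_noise * rnorm(d)
    }
  })
  colnames(emb) <- sprintf("e%03d", seq_len(d))
  emb
}

#' Pathway gene sets implied by a simulated ground truth
#'
#' @param truth A [simulate_deltas()] result.
#' @return Named list: pathway id -> character vector of member target genes.
#' @export
pathway_gene_sets <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  split(names(truth$pathways), paste0("pathway_", truth$pathways))
}

#' Simulate a complete synthetic benchmark instance
#'
#' Convenience wrapper running [simulate_deltas()], [simulate_cells()] and
#' [simulate_embeddings()] under one configuration.
#'
#' @param cfg A [sim_config()].
#' @return List with `truth`, `dataset` (raw counts), `embeddings`, and
#'   `gene_sets` (simulated pathway membership).
#' @export
simulate_benchmark <- function(cfg) {
  truth <- simulate_deltas(cfg)
  list(truth = truth,
       dataset = simulate_cells(cfg, truth),
       embeddings = simulate_embeddings(cfg, truth),
       gene_sets = pathway_gene_sets(truth))
}
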