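# Small deterministic fixtures shared across test files.

# hand-built 3-condition dataset: ctrl + 2 single perturbations over 4 genes,
# entries chosen so group means are easy to verify by hand
toy_dataset <- function(normalized = TRUE) {
  m <- rbind(
    c(1, 1, 1, 1), c(1, 3, 1, 1),            # ctrl
    c(2, 0, 1, 1), c(4, 0, 1, 3),            # gA
    c(0, 2, 2, 0), c(0, 4, 2, 2), c(0, 3, 2, 1)) # gB
  conds <- c("ctrl", "ctrl", "gA", "gA", "gB", "gB", "gB")
  perturb_dataset(m, conds, gene_names = c("gA", "gB", "gC", "gD"),
                  normalized = normalized)
}

# seeded normal dataset with a known mean shift on chosen genes, for DE tests
shifted_dataset <- function(n_per_group = 10, n_genes = 30, shift_genes = 1:3,
                            shift = 5, seed = 42) {
  withr::with_seed(seed, {
    genes <- sprintf("g%03d", seq_len(n_genes))
    ctrl <- matrix(rnorm(n_per_group * n_genes), n_per_group, n_genes)
    pert <- matrix(rnorm(n_per_group * n_genes), n_per_group, n_genes)
    pert[, shift_genes] <- pert[, shift_genes] + shift
    m <- abs(rbind(ctrl, pert)) # keep entries non-negative
    m[(n_per_group + 1):(2 * n_per_group), shift_genes] <-
      pert[, shift_genes] + 10  # well-separated positive values
    perturb_dataset(m, rep(c("ctrl", genes[1]), each = n_per_group),
                    gene_names = genes, normalized = TRUE)
  })
}

# small simulated benchmark instance for oracle tests; ... overrides defaults
small_sim <- function(seed = 1, ...) {
  args <- list(n_genes = 200, n_perturbations = 10, cells_per_condition = 15,
               control_cells = 60, count_depth = 2000, seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}
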