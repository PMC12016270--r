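#' Construct a Perturb-seq-style dataset
#'
#' Bundles a cells-by-genes expression matrix with per-cell condition labels.
#' A condition is either the control label or a perturbation label; combo
#' (dual) perturbations are written as the two target genes joined by
#' `combo_sep`, e.g. `"GATA1+KLF1"`. Each perturbation's target-gene set is
#' parsed from its label, so every label component must be a known gene name.
#'
#' @param matrix Numeric cells x genes matrix (raw counts or log-normalized),
#'   finite and non-negative.
#' @param conditions Character vector, one label per cell (row of `matrix`).
#' @param gene_names Character vector of unique gene identifiers, one per
#'   column. Defaults to `colnames(matrix)`.
#' @param control_label Label marking unperturbed cells. Default `"ctrl"`.
#' @param combo_sep Separator splitting combo labels into target genes.
#' @param normalized Logical; `TRUE` if `matrix` is already log-normalized
#'   (see [normalize_counts()]), `FALSE` for raw counts.
#'
#' @return An object of class `perturb_dataset`: a list with elements
#'   `matrix`, `conditions`, `gene_names`, `control_label`, `combo_sep`,
#'   `normalized`, and `targets` (named list mapping each perturbation label
#'   to its target gene names).
#' @export
perturb_dataset <- function(matrix, conditions, gene_names = colnames(matrix),
                            control_label = "ctrl", combo_sep = "+",
                            normalized = FALSE) {
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "double"
  if (is.null(gene_names)) {
    stop("gene names are required (gene_names or colnames(matrix))")
  }
  if (length(gene_names) != ncol(matrix)) {
    stop("length(gene_names) must equal ncol(matrix)")
  }
  if (anyDuplicated(gene_names)) stop("gene_names must be unique")
  if (length(conditions) != nrow(matrix)) {
    stop("one condition label is required per cell (row)")
  }
  if (!all(is.finite(matrix))) stop("matrix entries must be finite")
  if (any(matrix < 0)) stop("matrix entries must be non-negative")
  conditions <- as.character(conditions)
  if (!any(conditions == control_label)) {
    stop("dataset must contain at least one control cell (label '",
         control_label, "')")
  }
  colnames(matrix) <- gene_names
  perts <- setdiff(unique(conditions), control_label)
  targets <- parse_targets(perts, gene_names, combo_sep)
  structure(
    list(matrix = matrix, conditions = conditions, gene_names = gene_names,
         control_label = control_label, combo_sep = combo_sep,
         normalized = normalized, targets = targets),
    class = "perturb_dataset"
  )
}

#' Parse perturbation labels into target-gene sets
#'
#' Splits each label on `combo_sep` (at most two components) and checks every
#' component against the known gene names.
#'
#' @param labels Character vector of perturbation labels.
#' @param gene_names Known gene identifiers.
#' @param combo_sep Separator for combo labels.
#' @return Named list: label -> character vector of 1 or 2 target genes.
#' @export
parse_targets <- function(labels, gene_names, combo_sep = "+") {
  out <- lapply(labels, function(lab) {
    parts <- strsplit(lab, combo_sep, fixed = TRUE)[[1]]
    if (length(parts) < 1L || length(parts) > 2L) {
      stop("perturbation label '", lab, "' must have 1 or 2 components")
    }
    missing <- setdiff(parts, gene_names)
    if (length(missing)) {
      stop("perturbation label '", lab, "' refers to unknown gene(s): ",
           paste(missing, collapse = ", "))
    }
    parts
  })
  names(out) <- labels
  out
}

#' @export
print.perturb_dataset <- function(x, ...) {
  n_pert <- length(x$targets)
  n_combo <- sum(lengths(x$targets) == 2L)
  cat(sprintf(
    "perturb_dataset: %d cells x %d genes; %d perturbations (%d combos); %s\n",
    nrow(x$matrix), ncol(x$matrix), n_pert, n_combo,
    if (x$normalized) "log-normalized" else "raw counts"))
  cat(sprintf("  control label '%s': %d cells\n", x$control_label,
              sum(x$conditions == x$control_label)))
  invisible(x)
}

#' Library-size normalize and log-transform raw counts
#'
#' Rescales every cell to a fixed total count, then applies the natural-log
#' `log(1 + x)` transform — the single-cell ecosystem's standard
#' normalization (counts per 10,000, log1p). Cells with zero total count
#' cannot be rescaled and are dropped with a warning; the number dropped is
#' recorded in the `dropped_cells` attribute of the result.
#'
#' @param ds A raw-count [perturb_dataset()].
#' @param total Target total count per cell. Default 10000.
#' @return A log-normalized `perturb_dataset` (`normalized = TRUE`).
#' @export
normalize_counts <- function(ds, total = 1e4) {
  stopifnot(inherits(ds, "perturb_dataset"))
  if (isTRUE(ds$normalized)) stop("dataset is already log-normalized")
  totals <- rowSums(ds$matrix)
  keep <- totals > 0
  if (!any(keep)) stop("empty dataset after filtering: all cells have zero total count")
  n_dropped <- sum(!keep)
  if (n_dropped > 0L) {
    warning(n_dropped, " cell(s) with zero total count dropped")
  }
  m <- ds$matrix[keep, , drop = FALSE]
  m <- log1p(m / rowSums(m) * total)
  out <- perturb_dataset(m, ds$conditions[keep], ds$gene_names,
                         control_label = ds$control_label,
                         combo_sep = ds$combo_sep, normalized = TRUE)
  attr(out, "dropped_cells") <- n_dropped
  out
}

#' Read a dense cells-by-genes CSV as a perturb_dataset
#'
#' Expected layout: header row of gene names, first column holding the
#' per-cell condition label, remaining columns numeric expression.
#'
#' @param path CSV file path.
#' @param control_label,combo_sep,normalized Passed to [perturb_dataset()].
#' @return A [perturb_dataset()].
#' @export
read_perturb_csv <- function(path, control_label = "ctrl", combo_sep = "+",
                             normalized = FALSE) {
  dt <- data.table::fread(path, header = TRUE)
  conditions <- as.character(dt[[1L]])
  m <- as.matrix(dt[, -1L, drop = FALSE])
  perturb_dataset(m, conditions, colnames(m), control_label = control_label,
                  combo_sep = combo_sep, normalized = normalized)
}

#' Write a perturb_dataset to dense CSV
#'
#' Inverse of [read_perturb_csv()]: first column `condition`, then one column
#' per gene.
#'
#' @param ds A [perturb_dataset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_perturb_csv <- function(ds, path) {
  stopifnot(inherits(ds, "perturb_dataset"))
  dt <- data.table::data.table(condition = ds$conditions)
  dt <- cbind(dt, data.table::as.data.table(ds$matrix))
  data.table::fwrite(dt, path)
  invisible(path)
}
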