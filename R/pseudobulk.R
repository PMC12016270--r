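#' Pseudo-bulk a dataset: per-condition mean expression profiles
#'
#' Averages the log-normalized expression of all cells sharing a condition
#' label, giving one profile per condition. This is the unweighted arithmetic
#' mean over cells; no further library-size weighting is applied (cells were
#' already depth-normalized).
#'
#' @param ds A log-normalized [perturb_dataset()].
#' @return Conditions x genes numeric matrix; rownames are condition labels
#'   (control included), colnames the gene names.
#' @export
pseudobulk <- function(ds) {
  stopifnot(inherits(ds, "perturb_dataset"))
  if (!isTRUE(ds$normalized)) {
    stop("pseudobulk expects log-normalized data; run normalize_counts() first")
  }
  f <- factor(ds$conditions)
  n <- as.vector(table(f))
  pb <- rowsum(ds$matrix, f, reorder = TRUE) / n
  rownames(pb) <- levels(f)
  pb
}

#' Delta profiles: pseudo-bulk minus control
#'
#' Subtracts the control pseudo-bulk profile from every perturbed profile,
#' yielding the differential-expression (delta) signature of each
#' perturbation in log space. The control row itself is not part of the
#' output.
#'
#' @param pb Conditions x genes pseudo-bulk matrix (see [pseudobulk()]).
#' @param control_label Row name of the control profile.
#' @return Perturbations x genes matrix of deltas, with the control label
#'   recorded in the `"control_label"` attribute.
#' @export
delta_profiles <- function(pb, control_label = "ctrl") {
  if (!control_label %in% rownames(pb)) {
    stop("control label '", control_label, "' not found in pseudo-bulk matrix")
  }
  ctrl <- pb[control_label, ]
  d <- sweep(pb[setdiff(rownames(pb), control_label), , drop = FALSE], 2L, ctrl)
  attr(d, "control_label") <- control_label
  d
}

#' Write a profile matrix (pseudo-bulk or delta) as CSV
#'
#' One row per condition, header row of gene names, first column `condition`.
#'
#' @param mat Conditions x genes matrix with rownames.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_profiles_csv <- function(mat, path) {
  dt <- data.table::data.table(condition = rownames(mat))
  dt <- cbind(dt, data.table::as.data.table(mat))
  data.table::fwrite(dt, path)
  invisible(path)
}

#' Read a profile matrix written by [write_profiles_csv()]
#'
#' @param path CSV file path.
#' @return Conditions x genes matrix with condition rownames.
#' @export
read_profiles_csv <- function(path) {
  dt <- data.table::fread(path, header = TRUE)
  m <- as.matrix(dt[, -1L, drop = FALSE])
  rownames(m) <- as.character(dt[[1L]])
  m
}
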