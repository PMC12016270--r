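#' Read a gene-embedding table from TSV
#'
#' Expected layout: first column gene identifier, remaining columns numeric
#' embedding dimensions, with a header row. Embedding tables are plain
#' genes x dimensions numeric matrices with unique gene rownames.
#'
#' @param path TSV file path.
#' @return Genes x d numeric matrix with gene rownames.
#' @export
read_embedding_tsv <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t")
  genes <- as.character(dt[[1L]])
  if (anyDuplicated(genes)) stop("duplicate gene identifiers in ", path)
  m <- as.matrix(dt[, -1L, drop = FALSE])
  if (!is.numeric(m) || !all(is.finite(m))) {
    stop("embedding values must be finite numerics")
  }
  rownames(m) <- genes
  m
}

#' Write a gene-embedding table to TSV
#'
#' @param emb Genes x d matrix with gene rownames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_embedding_tsv <- function(emb, path) {
  dt <- data.table::data.table(gene = rownames(emb))
  dt <- cbind(dt, data.table::as.data.table(emb))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' GMT is the tab-delimited gene-set format: one set per line as
#' `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path GMT file path.
#' @return Named list of character vectors (set name -> member genes).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L) stop("malformed GMT line: ", substr(l, 1, 60))
    unique(parts[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1L), USE.NAMES = FALSE)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Description field written for every set.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, description, sets[[nm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Binary gene-by-set membership matrix from gene sets
#'
#' Builds the 0/1 incidence matrix used as a GO-style embedding: genes as
#' rows, sets as columns, 1 where the gene belongs to the set. Sets with
#' fewer than `min_set_size` member genes in `genes` are dropped (tiny sets
#' carry almost no featurization signal); the number dropped is reported in
#' the `"dropped_sets"` attribute.
#'
#' @param sets Named list of gene sets (e.g. from [read_gmt()]).
#' @param genes Gene universe defining the rows.
#' @param min_set_size Minimum member genes per retained set. Default 3.
#' @return Genes x sets binary matrix with dimnames.
#' @export
gene_set_matrix <- function(sets, genes, min_set_size = 3L) {
  keep <- vapply(sets, function(s) sum(s %in% genes) >= min_set_size, logical(1L))
  kept <- sets[keep]
  m <- matrix(0, length(genes), length(kept),
              dimnames = list(genes, names(kept)))
  for (nm in names(kept)) {
    m[intersect(kept[[nm]], genes), nm] <- 1
  }
  attr(m, "dropped_sets") <- sum(!keep)
  m
}
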