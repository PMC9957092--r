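# Single-cell quality control and library-size normalization.

#' Filter low-quality cells and rarely detected genes
#'
#' Applies the standard single-cell QC rules to a raw count matrix, in a
#' fixed order: first cells, then genes. A cell is removed when it has fewer
#' than `min_genes_per_cell` detected (nonzero) genes or when more than
#' `max_mito_fraction` of its counts come from mitochondrial genes; a gene is
#' then removed when it is detected in fewer than `min_cells_per_gene` of the
#' *retained* cells. Values are never altered, only rows/columns dropped.
#'
#' Mitochondrial genes are recognized by an identifier prefix (default
#' `"MT-"`, the human HGNC convention).
#'
#' @param counts an [expression_matrix()] of raw counts (`is_log_scale` must
#'   be `FALSE`).
#' @param mito_prefix gene-id prefix marking mitochondrial genes.
#' @param min_genes_per_cell minimum detected genes per retained cell.
#' @param max_mito_fraction maximum mitochondrial count fraction per cell.
#' @param min_cells_per_gene minimum retained cells a gene must be detected in.
#' @return The filtered [expression_matrix()] (a submatrix of the input).
#' @export
qc_filter_cells_genes <- function(counts, mito_prefix = "MT-",
                                  min_genes_per_cell = 200L,
                                  max_mito_fraction = 0.20,
                                  min_cells_per_gene = 3L) {
  if (counts$is_log_scale) scdr_abort("QC expects raw counts, not log-scale values")
  v <- counts$values
  detected <- Matrix::colSums(v > 0)
  total <- Matrix::colSums(v)
  mito <- startsWith(gene_ids(counts), mito_prefix)
  mito_counts <- if (any(mito)) Matrix::colSums(v[mito, , drop = FALSE]) else
    rep(0, ncol(v))
  mito_frac <- ifelse(total > 0, mito_counts / total, 1)
  keep_cells <- detected >= min_genes_per_cell & mito_frac <= max_mito_fraction
  if (!any(keep_cells)) scdr_abort("empty after QC: every cell failed the filters",
                                   "scdr_qc_error")
  v <- v[, keep_cells, drop = FALSE]
  gene_cells <- Matrix::rowSums(v > 0)
  keep_genes <- gene_cells >= min_cells_per_gene
  v <- v[keep_genes, , drop = FALSE]
  n_cells_dropped <- sum(!keep_cells)
  n_genes_dropped <- sum(!keep_genes)
  if (n_cells_dropped || n_genes_dropped) {
    message(sprintf("QC removed %d cell(s) and %d gene(s)",
                    n_cells_dropped, n_genes_dropped))
  }
  expression_matrix(v, is_log_scale = FALSE)
}

#' Library-size normalize raw counts
#'
#' Divides each cell's counts by its total, multiplies by `scale`, and
#' applies the natural log1p transform — the conventional per-cell
#' normalization for UMI count data. The output is flagged log-scale.
#'
#' @param counts an [expression_matrix()] of raw counts.
#' @param scale target library size after rescaling (default 10,000).
#' @return A log-scale [expression_matrix()]; for every cell,
#'   `sum(expm1(column))` equals `scale`.
#' @export
normalize_counts <- function(counts, scale = 1e4) {
  if (counts$is_log_scale) scdr_abort("counts are already log-scale")
  v <- counts$values
  total <- Matrix::colSums(v)
  if (any(total == 0)) {
    scdr_abort(paste0("cell(s) with zero total counts: ",
                      oxford_head(colnames(v)[total == 0]),
                      "; run qc_filter_cells_genes() first"))
  }
  if (methods::is(v, "Matrix")) {
    v <- v %*% Matrix::Diagonal(x = scale / total)
    v <- methods::as(v, "CsparseMatrix")
    v@x <- log1p(v@x)
    dimnames(v) <- dimnames(counts$values)
  } else {
    v <- log1p(sweep(v, 2L, total / scale, `/`))
  }
  expression_matrix(v, is_log_scale = TRUE)
}
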