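#' Gene-by-sample expression matrix
#'
#' Light container for a genes x samples expression matrix. Values may be a
#' base dense matrix or a `Matrix` sparse matrix (single-cell counts); gene
#' and sample identifiers live in the dimnames. The `is_log_scale` flag
#' records whether values have been log-transformed, which downstream
#' signature derivation checks before taking ratios of row means.
#'
#' Invariants enforced at construction: unique non-empty gene and sample ids,
#' all values finite, and all values non-negative when `is_log_scale` is
#' `FALSE`.
#'
#' @param values numeric matrix (base or `Matrix` sparse), genes in rows,
#'   samples in columns, with complete dimnames.
#' @param is_log_scale logical; `TRUE` if values are on a log scale.
#' @return An object of class `expression_matrix`: a list with elements
#'   `values` and `is_log_scale`.
#' @examples
#' m <- matrix(1:6, nrow = 3, dimnames = list(c("G1", "G2", "G3"), c("S1", "S2")))
#' em <- expression_matrix(m)
#' dim(em)
#' @export
expression_matrix <- function(values, is_log_scale = FALSE) {
  if (!(is.matrix(values) || methods::is(values, "Matrix"))) {
    scdr_abort("`values` must be a base matrix or a Matrix sparse matrix")
  }
  gn <- rownames(values)
  sn <- colnames(values)
  if (is.null(gn) || is.null(sn) || any(!nzchar(gn)) || any(!nzchar(sn))) {
    scdr_abort("expression matrix needs non-empty gene and sample identifiers")
  }
  if (anyDuplicated(gn)) {
    scdr_abort(paste0("duplicate gene ids: ", oxford_head(unique(gn[duplicated(gn)]))))
  }
  if (anyDuplicated(sn)) {
    scdr_abort(paste0("duplicate sample ids: ", oxford_head(unique(sn[duplicated(sn)]))))
  }
  vals <- if (methods::is(values, "Matrix")) values@x else values
  if (length(vals) && any(!is.finite(vals))) {
    scdr_abort("expression values must all be finite")
  }
  if (!is_log_scale && length(vals) && any(vals < 0)) {
    scdr_abort("negative values in a matrix declared linear-scale; set is_log_scale = TRUE if these are log-ratios")
  }
  structure(list(values = values, is_log_scale = isTRUE(is_log_scale)),
            class = "expression_matrix")
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Gene identifiers of an expression matrix
#' @param x an `expression_matrix`.
#' @return Character vector of gene ids (row order).
#' @export
gene_ids <- function(x) rownames(x$values)

#' Sample identifiers of an expression matrix
#' @param x an `expression_matrix`.
#' @return Character vector of sample ids (column order).
#' @export
sample_ids <- function(x) colnames(x$values)

#' @export
print.expression_matrix <- function(x, ...) {
  kind <- if (methods::is(x$values, "Matrix")) "sparse" else "dense"
  cat(sprintf("<expression_matrix> %d genes x %d samples (%s, %s scale)\n",
              nrow(x$values), ncol(x$values), kind,
              if (x$is_log_scale) "log" else "linear"))
  invisible(x)
}

#' @export
as.matrix.expression_matrix <- function(x, ...) as.matrix(x$values)

# Internal: subset preserving class and flag.
em_subset <- function(em, genes = NULL, samples = NULL) {
  v <- em$values
  if (!is.null(genes)) v <- v[genes, , drop = FALSE]
  if (!is.null(samples)) v <- v[, samples, drop = FALSE]
  expression_matrix(v, em$is_log_scale)
}
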