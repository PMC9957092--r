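# Drug-response scoring: gene-wise z-standardization of the profile being
# scored, followed by the fold-change-weighted mean over signature genes.

#' Gene-wise z-score standardization
#'
#' Standardizes every gene across the samples of the dataset being scored:
#' `z = (exp - mean) / sd`, with the mean and sample standard deviation
#' (n - 1) taken over all samples of this matrix. Statistics are always
#' computed on the data at hand, never carried over from a training cohort.
#' Genes with zero variance cannot be standardized and are removed (their
#' ids are kept in the result for reporting).
#'
#' Sparse inputs are densified in gene-row batches; the result is always a
#' dense matrix (z-scores are dense by construction).
#'
#' @param expr an [expression_matrix()] with at least two samples.
#' @param batch_rows rows per densification batch for sparse input.
#' @return A `zscore_matrix`: list with `values` (dense genes x samples
#'   matrix of z-scores) and `dropped_genes` (zero-variance gene ids).
#' @export
zscore_transform <- function(expr, batch_rows = 512L) {
  v <- expr$values
  if (ncol(v) < 2L) scdr_abort("z-scores need at least two samples (sd undefined)")
  n <- ncol(v)
  z <- matrix(NA_real_, nrow = nrow(v), ncol = n, dimnames = dimnames(v))
  keep <- logical(nrow(v))
  starts <- seq(1L, nrow(v), by = batch_rows)
  for (s in starts) {
    idx <- s:min(s + batch_rows - 1L, nrow(v))
    d <- as.matrix(v[idx, , drop = FALSE])
    mu <- rowMeans(d)
    dev <- d - mu
    sdv <- sqrt(rowSums(dev * dev) / (n - 1L))
    ok <- sdv > 1e-12 * (1 + abs(mu))
    keep[idx] <- ok
    z[idx[ok], ] <- dev[ok, , drop = FALSE] / sdv[ok]
  }
  dropped <- rownames(v)[!keep]
  if (length(dropped)) {
    message(sprintf("dropped %d zero-variance gene(s) before scoring", length(dropped)))
  }
  structure(list(values = z[keep, , drop = FALSE], dropped_genes = dropped),
            class = "zscore_matrix")
}

#' Score all samples against one drug signature
#'
#' The drug-response score of sample `m` is the mean, over the `q` signature
#' genes present in the z-score matrix, of `log2FC_i * z_im`. Higher scores
#' predict resistance. `q` counts the intersection of signature genes with
#' the scoreable (non-constant) genes of the profile.
#'
#' @param z a `zscore_matrix` from [zscore_transform()].
#' @param signature a [drug_signature()].
#' @return A `drs_row`: list with `drug`, `scores` (named numeric per
#'   sample), and `q_used`.
#' @export
score_samples <- function(z, signature) {
  genes <- intersect(signature$gene, rownames(z$values))
  if (!length(genes)) {
    scdr_abort(sprintf("no signature genes present in the expression profile for drug '%s'",
                       attr(signature, "drug")), "scdr_empty_intersection")
  }
  w <- signature$log2fc[match(genes, signature$gene)]
  drs <- colSums(z$values[genes, , drop = FALSE] * w) / length(genes)
  structure(list(drug = attr(signature, "drug"), scores = drs,
                 q_used = length(genes)),
            class = "drs_row")
}

#' Score an expression profile against many drug signatures
#'
#' Computes the z-transform once and reuses it across drugs. Drugs whose
#' signatures share no genes with the profile are skipped with a report.
#'
#' @param expr the [expression_matrix()] to score (bulk samples or cells).
#' @param signatures list of [drug_signature()] objects.
#' @return A `drs_matrix`: list with `scores` (drugs x samples), `q_used`
#'   (named integer per drug) and `skipped` (drugs without any shared gene).
#' @export
score_all <- function(expr, signatures) {
  z <- zscore_transform(expr)
  drugs <- vapply(signatures, function(s) attr(s, "drug"), character(1L))
  rows <- vector("list", length(signatures))
  skipped <- character()
  for (i in seq_along(signatures)) {
    res <- tryCatch(score_samples(z, signatures[[i]]),
                    scdr_empty_intersection = function(e) NULL)
    if (is.null(res)) skipped <- c(skipped, drugs[i]) else rows[i] <- list(res)
  }
  ok <- !vapply(rows, is.null, logical(1L))
  if (!any(ok)) scdr_abort("every drug was skipped: no signature genes in the profile")
  if (length(skipped)) {
    message(sprintf("skipped %d drug(s) with empty gene intersection: %s",
                    length(skipped), oxford_head(skipped)))
  }
  scores <- do.call(rbind, lapply(rows[ok], `[[`, "scores"))
  rownames(scores) <- drugs[ok]
  q <- vapply(rows[ok], `[[`, integer(1L), "q_used")
  names(q) <- drugs[ok]
  structure(list(scores = scores, q_used = q, skipped = skipped),
            class = "drs_matrix")
}

#' @export
print.drs_matrix <- function(x, ...) {
  cat(sprintf("<drs_matrix> %d drug(s) x %d sample(s)\n",
              nrow(x$scores), ncol(x$scores)))
  invisible(x)
}

#' Aggregate cell-level scores to cell-line means (mDRS)
#'
#' Single-cell predictions are validated at the cell-line level: for every
#' drug and line, the mDRS is the arithmetic mean DRS over the line's cells.
#'
#' @param drs a `drs_matrix` over cells.
#' @param cell_to_line a [sample_grouping()] mapping every scored cell to its
#'   cell line.
#' @return A `drs_matrix` whose columns are cell lines.
#' @export
aggregate_mdrs <- function(drs, cell_to_line) {
  cells <- colnames(drs$scores)
  idx <- match(cells, cell_to_line$sample_id)
  if (anyNA(idx)) {
    scdr_abort(paste0("scored cell(s) missing from the cell-to-line map: ",
                      oxford_head(cells[is.na(idx)])))
  }
  line <- cell_to_line$group[idx]
  agg <- t(rowsum(t(drs$scores), group = line, reorder = FALSE))
  counts <- as.vector(table(line)[colnames(agg)])
  agg <- sweep(agg, 2L, counts, `/`)
  structure(list(scores = agg, q_used = drs$q_used, skipped = drs$skipped),
            class = "drs_matrix")
}
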