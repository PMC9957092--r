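# Resistant/sensitive labelling from AUC values and drug-response-gene
# (DRG) signature derivation by group-mean fold change.

#' Label cell lines resistant or sensitive for one drug
#'
#' For a drug, the AUC (area under the percent-viability curve) of every
#' profiled cell line is compared with the cohort mean: lines with
#' `AUC > mean + k*sd` are labelled resistant (R) and lines with
#' `AUC < mean - k*sd` sensitive (S); lines in the middle band stay
#' unlabelled. Inequalities are strict, and `sd` is the sample standard
#' deviation (n - 1 denominator).
#'
#' @param responses a [drug_response_table()].
#' @param drug drug identifier present in `responses`.
#' @param k threshold multiplier on the AUC standard deviation (default 0.8).
#' @param min_group_size minimum lines required on each side (default 2).
#' @return A `response_labels` object: list with `drug`, `resistant`,
#'   `sensitive`, `auc_mean`, `auc_sd`, `k`.
#' @export
classify_cell_lines <- function(responses, drug, k = 0.8, min_group_size = 2L) {
  rec <- responses[responses$drug == drug, , drop = FALSE]
  if (nrow(rec) < 3L) {
    scdr_abort(sprintf("drug '%s' has %d profiled line(s); need at least 3",
                       drug, nrow(rec)), "scdr_insufficient_group")
  }
  mu <- mean(rec$auc)
  s <- stats::sd(rec$auc)
  if (s == 0) {
    scdr_abort(sprintf("degenerate response distribution for drug '%s' (all AUC equal)", drug),
               "scdr_degenerate")
  }
  resistant <- rec$cell_line[rec$auc > mu + k * s]
  sensitive <- rec$cell_line[rec$auc < mu - k * s]
  if (length(resistant) < min_group_size || length(sensitive) < min_group_size) {
    scdr_abort(sprintf("insufficient group for drug '%s': %d resistant, %d sensitive (need >= %d each)",
                       drug, length(resistant), length(sensitive), min_group_size),
               "scdr_insufficient_group")
  }
  response_labels(drug, resistant, sensitive, auc_mean = mu, auc_sd = s, k = k)
}

#' Construct a resistant/sensitive label set
#'
#' @param drug drug identifier.
#' @param resistant,sensitive disjoint character vectors of cell-line ids.
#' @param auc_mean,auc_sd,k the labelling statistics (optional when labels
#'   come from an external source, e.g. clinical response classes).
#' @return A `response_labels` object.
#' @export
response_labels <- function(drug, resistant, sensitive,
                            auc_mean = NA_real_, auc_sd = NA_real_, k = NA_real_) {
  resistant <- unique(as.character(resistant))
  sensitive <- unique(as.character(sensitive))
  both <- intersect(resistant, sensitive)
  if (length(both)) {
    scdr_abort(paste0("line(s) labelled both resistant and sensitive: ", oxford_head(both)))
  }
  structure(list(drug = drug, resistant = resistant, sensitive = sensitive,
                 auc_mean = auc_mean, auc_sd = auc_sd, k = k),
            class = "response_labels")
}

#' @export
print.response_labels <- function(x, ...) {
  cat(sprintf("<response_labels> drug %s: %d resistant, %d sensitive (k = %s)\n",
              x$drug, length(x$resistant), length(x$sensitive), format(x$k)))
  invisible(x)
}

#' Construct/validate a drug signature
#'
#' @param drug drug identifier.
#' @param genes character vector of signature gene ids (no duplicates).
#' @param log2fc numeric log2 fold-change weights, same length; positive for
#'   up-regulated-in-resistant genes, negative for down-regulated.
#' @return A `drug_signature`: data frame (`gene`, `log2fc`) with attributes
#'   `drug`, `n_up`, `n_down`.
#' @export
drug_signature <- function(drug, genes, log2fc) {
  genes <- as.character(genes)
  stopifnot(length(genes) == length(log2fc))
  if (anyDuplicated(genes)) {
    scdr_abort(paste0("duplicate signature genes: ",
                      oxford_head(unique(genes[duplicated(genes)]))))
  }
  if (any(is.na(log2fc)) || any(log2fc == 0)) {
    scdr_abort("signature weights must be nonzero and non-missing")
  }
  df <- data.frame(gene = genes, log2fc = as.numeric(log2fc), stringsAsFactors = FALSE)
  structure(df, drug = drug, n_up = sum(log2fc > 0), n_down = sum(log2fc < 0),
            class = c("drug_signature", "data.frame"))
}

#' Derive the drug-response-gene signature for one drug
#'
#' Computes, for every gene, the log2 fold change between the mean linear-
#' scale expression of resistant and sensitive training lines,
#' `log2((mean_R + pseudocount) / (mean_S + pseudocount))`, then keeps the
#' `n_top` most up-regulated (largest positive log2FC) and `n_top` most
#' down-regulated genes as the drug-response genes, each weighted by its
#' log2FC. Genes with zero mean in both groups are dropped rather than
#' scored 0. Ranking ties are broken by gene id so builds are deterministic.
#'
#' Fold changes are ratios of linear-scale row means; a matrix flagged
#' `is_log_scale` is rejected unless `allow_log_scale = TRUE` (in which case
#' means are taken on the log scale, which is a different statistic — make
#' the choice consciously).
#'
#' @param expr training [expression_matrix()] containing the labelled lines.
#' @param labels a `response_labels` object (see [classify_cell_lines()]).
#' @param n_top genes kept per direction (default 200).
#' @param pseudocount added to both group means before the ratio
#'   (default 0.01; 0 allowed, in which case genes unexpressed in one group
#'   get infinite log2FC and rank first).
#' @param allow_log_scale set `TRUE` to acknowledge log-scale input.
#' @return A [drug_signature()].
#' @export
derive_signature <- function(expr, labels, n_top = 200L, pseudocount = 0.01,
                             allow_log_scale = FALSE) {
  if (expr$is_log_scale && !allow_log_scale) {
    scdr_abort(paste0("expression is flagged log-scale; fold changes are defined on ",
                      "linear-scale means. De-log the matrix or pass ",
                      "allow_log_scale = TRUE to take means on the log scale."))
  }
  r_cols <- intersect(labels$resistant, sample_ids(expr))
  s_cols <- intersect(labels$sensitive, sample_ids(expr))
  if (!length(r_cols) || !length(s_cols)) {
    scdr_abort(sprintf("drug '%s': expression matrix has %d resistant and %d sensitive column(s); need >= 1 of each",
                       labels$drug, length(r_cols), length(s_cols)))
  }
  mean_r <- Matrix::rowMeans(expr$values[, r_cols, drop = FALSE])
  mean_s <- Matrix::rowMeans(expr$values[, s_cols, drop = FALSE])
  keep <- !(mean_r == 0 & mean_s == 0)
  # difference of logs rather than log of ratio: bit-exact antisymmetry
  # under a resistant/sensitive label swap
  l2fc <- log2(mean_r[keep] + pseudocount) - log2(mean_s[keep] + pseudocount)
  genes <- gene_ids(expr)[keep]
  up_idx <- which(l2fc > 0)
  up_idx <- up_idx[order(-l2fc[up_idx], genes[up_idx])]
  down_idx <- which(l2fc < 0)
  down_idx <- down_idx[order(l2fc[down_idx], genes[down_idx])]
  if (length(up_idx) < n_top || length(down_idx) < n_top) {
    message(sprintf("drug '%s': only %d up / %d down genes available for n_top = %d",
                    labels$drug, length(up_idx), length(down_idx), n_top))
  }
  up_idx <- head(up_idx, n_top)
  down_idx <- head(down_idx, n_top)
  if (!length(up_idx) && !length(down_idx)) {
    scdr_abort(sprintf("drug '%s': no genes with nonzero fold change", labels$drug))
  }
  sel <- c(up_idx, down_idx)
  drug_signature(labels$drug, genes[sel], l2fc[sel])
}

#' Derive signatures for every drug in a response table
#'
#' Iterates [classify_cell_lines()] + [derive_signature()] over all drugs.
#' Drugs failing labelling (degenerate AUC distribution or too few lines on
#' one side) are skipped and reported, not fatal.
#'
#' @inheritParams derive_signature
#' @param responses a [drug_response_table()] covering one or more drugs.
#' @param k threshold multiplier for [classify_cell_lines()].
#' @param min_group_size minimum lines per side for labelling.
#' @return Named list of [drug_signature()] objects with attribute `skipped`,
#'   a data frame (`drug`, `reason`) of drugs that produced no signature.
#' @export
derive_all_signatures <- function(expr, responses, k = 0.8, n_top = 200L,
                                  pseudocount = 0.01, min_group_size = 2L,
                                  allow_log_scale = FALSE) {
  drugs <- unique(responses$drug)
  sigs <- list()
  skipped <- data.frame(drug = character(), reason = character(),
                        stringsAsFactors = FALSE)
  for (d in drugs) {
    res <- tryCatch({
      lab <- classify_cell_lines(responses, d, k = k, min_group_size = min_group_size)
      derive_signature(expr, lab, n_top = n_top, pseudocount = pseudocount,
                       allow_log_scale = allow_log_scale)
    }, scdr_insufficient_group = function(e) e, scdr_degenerate = function(e) e)
    if (inherits(res, "condition")) {
      skipped <- rbind(skipped, data.frame(drug = d, reason = conditionMessage(res),
                                           stringsAsFactors = FALSE))
    } else {
      sigs[[d]] <- res
    }
  }
  if (!length(sigs)) scdr_abort("no drug yielded a signature")
  if (nrow(skipped)) {
    message(sprintf("skipped %d drug(s) without a signature: %s",
                    nrow(skipped), oxford_head(skipped$drug)))
  }
  attr(sigs, "skipped") <- skipped
  sigs
}

#' Pairwise Jaccard overlap between drug signatures
#'
#' @param signatures list (length >= 2) of [drug_signature()] objects.
#' @return Symmetric drug x drug matrix of Jaccard indices between the
#'   signatures' gene sets; the diagonal is 1.
#' @export
signature_overlap <- function(signatures) {
  if (length(signatures) < 2L) scdr_abort("need at least two signatures")
  sets <- lapply(signatures, function(s) unique(s$gene))
  drugs <- vapply(signatures, function(s) attr(s, "drug"), character(1L))
  n <- length(sets)
  m <- diag(1, n)
  dimnames(m) <- list(drugs, drugs)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      inter <- length(intersect(sets[[i]], sets[[j]]))
      uni <- length(union(sets[[i]], sets[[j]]))
      m[i, j] <- m[j, i] <- if (uni == 0L) 0 else inter / uni
    }
  }
  m
}
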