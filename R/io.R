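# Readers and writers for every on-disk format the pipeline touches.
# Dense expression: delimited text, header row of sample ids, first column
# gene ids. Sparse expression: MatrixMarket coordinate triplet + feature and
# barcode lists (10x layout, 1-based indices). Tables: plain CSV/TSV.

infer_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

read_delim_checked <- function(path, sep, header = TRUE) {
  if (!file.exists(path)) scdr_abort(paste0("file not found: ", path), "scdr_io_error")
  tryCatch(
    data.table::fread(path, sep = sep, header = header, data.table = FALSE,
                      fill = FALSE, check.names = FALSE),
    error = function(e) scdr_abort(paste0("failed to parse ", path, ": ",
                                          conditionMessage(e)), "scdr_parse_error")
  )
}

#' Read a dense expression matrix from delimited text
#'
#' Reads a TSV/CSV with one header row and one identifier column into an
#' [expression_matrix()] in genes x samples orientation, regardless of the
#' on-disk orientation. Rows sharing a gene id are collapsed by their mean
#' (with a warning); duplicate sample ids are an error.
#'
#' @param path file path. Delimiter is inferred from the extension
#'   (`.csv` comma, anything else tab) unless `sep` is given.
#' @param orientation `"genes_in_rows"` (default) if rows are genes, or
#'   `"samples_in_rows"` for the transposed layout.
#' @param log_flag logical; declare the stored values log-transformed.
#' @param sep optional delimiter override.
#' @return An [expression_matrix()].
#' @export
read_expression_dense <- function(path,
                                  orientation = c("genes_in_rows", "samples_in_rows"),
                                  log_flag = FALSE, sep = NULL) {
  orientation <- match.arg(orientation)
  if (is.null(sep)) sep <- infer_sep(path)
  df <- read_delim_checked(path, sep)
  if (ncol(df) < 2L) scdr_abort("expression file needs an id column plus at least one data column",
                                "scdr_parse_error")
  ids <- trimws(as.character(df[[1L]]))
  header <- trimws(names(df)[-1L])   # keep duplicates: data.frame subsetting mangles them
  mat <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(mat)) scdr_abort("non-numeric expression values", "scdr_parse_error")
  rownames(mat) <- ids
  colnames(mat) <- header
  if (orientation == "samples_in_rows") mat <- t(mat)
  # rows are now genes; collapse duplicate gene rows by mean
  if (anyDuplicated(rownames(mat))) {
    dup <- unique(rownames(mat)[duplicated(rownames(mat))])
    warning(sprintf("collapsing %d duplicated gene id(s) by mean: %s",
                    length(dup), oxford_head(dup)))
    summed <- rowsum(mat, group = rownames(mat), reorder = FALSE)
    mat <- summed / as.vector(table(rownames(mat))[rownames(summed)])
  }
  if (anyDuplicated(colnames(mat))) {
    scdr_abort(paste0("duplicate sample ids: ",
                      oxford_head(unique(colnames(mat)[duplicated(colnames(mat))]))))
  }
  expression_matrix(mat, is_log_scale = log_flag)
}

#' Write a dense expression matrix to delimited text
#'
#' @param em an [expression_matrix()] (densified on write).
#' @param path output path; delimiter inferred from the extension.
#' @param sep optional delimiter override.
#' @return `path`, invisibly.
#' @export
write_expression_dense <- function(em, path, sep = NULL) {
  if (is.null(sep)) sep <- infer_sep(path)
  df <- data.frame(gene = gene_ids(em), as.matrix(em$values),
                   check.names = FALSE, stringsAsFactors = FALSE)
  data.table::fwrite(df, path, sep = sep)
  invisible(path)
}

#' Read 10x-style sparse expression (MatrixMarket + feature/barcode lists)
#'
#' @param matrix_path MatrixMarket coordinate file of raw counts.
#' @param genes_path newline-delimited gene list (first tab field used).
#' @param barcodes_path newline-delimited cell barcode list.
#' @return A sparse-backed [expression_matrix()] of raw counts.
#' @export
read_expression_mtx <- function(matrix_path, genes_path, barcodes_path) {
  for (p in c(matrix_path, genes_path, barcodes_path)) {
    if (!file.exists(p)) scdr_abort(paste0("file not found: ", p), "scdr_io_error")
  }
  m <- tryCatch(Matrix::readMM(matrix_path),
                error = function(e) scdr_abort(paste0("failed to parse ", matrix_path,
                                                      ": ", conditionMessage(e)),
                                               "scdr_parse_error"))
  genes <- trimws(vapply(strsplit(readLines(genes_path), "\t", fixed = TRUE),
                         `[`, character(1L), 1L))
  cells <- trimws(vapply(strsplit(readLines(barcodes_path), "\t", fixed = TRUE),
                         `[`, character(1L), 1L))
  if (nrow(m) != length(genes)) {
    scdr_abort(sprintf("matrix declares %d rows but gene list has %d entries",
                       nrow(m), length(genes)), "scdr_parse_error")
  }
  if (ncol(m) != length(cells)) {
    scdr_abort(sprintf("matrix declares %d columns but barcode list has %d entries",
                       ncol(m), length(cells)), "scdr_parse_error")
  }
  m <- methods::as(m, "CsparseMatrix")
  dimnames(m) <- list(genes, cells)
  expression_matrix(m, is_log_scale = FALSE)
}

#' Write a sparse expression matrix as a MatrixMarket triplet
#'
#' Writes `matrix.mtx`, `features.tsv` and `barcodes.tsv` into `dir`.
#'
#' @param em an [expression_matrix()].
#' @param dir output directory (created if needed).
#' @return Named character vector of the three paths, invisibly.
#' @export
write_expression_mtx <- function(em, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(matrix = file.path(dir, "matrix.mtx"),
             genes = file.path(dir, "features.tsv"),
             barcodes = file.path(dir, "barcodes.tsv"))
  m <- em$values
  if (!methods::is(m, "Matrix")) m <- Matrix::Matrix(m, sparse = TRUE)
  Matrix::writeMM(methods::as(m, "CsparseMatrix"), paths[["matrix"]])
  writeLines(gene_ids(em), paths[["genes"]])
  writeLines(sample_ids(em), paths[["barcodes"]])
  invisible(paths)
}

#' Read a long-format drug-response table
#'
#' Expects a delimited file with columns `cell_line`, `drug`, `auc` (the area
#' under the percent-viability dose-response curve; higher = more resistant).
#' Exact duplicate records are dropped; duplicates that disagree on AUC are
#' an error.
#'
#' @param path CSV/TSV path.
#' @return A `drug_response_table` data frame.
#' @export
read_drug_response <- function(path) {
  df <- read_delim_checked(path, infer_sep(path))
  need <- c("cell_line", "drug", "auc")
  if (!all(need %in% names(df))) {
    scdr_abort(paste0("drug-response table must have columns ",
                      paste(need, collapse = ", ")), "scdr_parse_error")
  }
  auc_raw <- df[["auc"]]
  auc <- suppressWarnings(as.numeric(auc_raw))
  bad <- which(!is.finite(auc))
  if (length(bad)) {
    scdr_abort(paste0("non-numeric AUC at line(s) ",
                      oxford_head(as.character(bad + 1L)), " of ", path),
               "scdr_parse_error")
  }
  drug_response_table(data.frame(cell_line = trimws(as.character(df[["cell_line"]])),
                                 drug = trimws(as.character(df[["drug"]])),
                                 auc = auc, stringsAsFactors = FALSE))
}

#' Construct/validate a drug-response table
#'
#' @param df data frame with columns `cell_line`, `drug`, `auc`.
#' @return The validated, deduplicated table with class `drug_response_table`.
#' @export
drug_response_table <- function(df) {
  stopifnot(is.data.frame(df), all(c("cell_line", "drug", "auc") %in% names(df)))
  if (any(!is.finite(df$auc))) scdr_abort("AUC values must be finite")
  df <- unique(df[, c("cell_line", "drug", "auc")])
  key <- paste(df$cell_line, df$drug, sep = "\r")
  if (anyDuplicated(key)) {
    off <- unique(key[duplicated(key)])
    scdr_abort(paste0("conflicting AUC values for (cell_line, drug) pair(s): ",
                      oxford_head(gsub("\r", " / ", off))))
  }
  rownames(df) <- NULL
  class(df) <- c("drug_response_table", "data.frame")
  df
}

#' Write a drug-response table
#' @param responses a `drug_response_table`.
#' @param path output CSV/TSV path.
#' @return `path`, invisibly.
#' @export
write_drug_response <- function(responses, path) {
  data.table::fwrite(as.data.frame(responses), path, sep = infer_sep(path))
  invisible(path)
}

#' Read a sample-to-group assignment
#'
#' Two-column TSV `sample_id<TAB>group`; a header row with those names is
#' optional and skipped if present. Carries resistant/sensitive labels,
#' cluster names, or cell-to-cell-line maps.
#'
#' @param path TSV path.
#' @return A `sample_grouping` data frame with columns `sample_id`, `group`.
#' @export
read_sample_grouping <- function(path) {
  df <- read_delim_checked(path, "\t", header = FALSE)
  if (ncol(df) != 2L) scdr_abort("grouping file must have exactly two columns",
                                 "scdr_parse_error")
  names(df) <- c("sample_id", "group")
  if (nrow(df) && identical(tolower(trimws(as.character(df[1L, ]))),
                            c("sample_id", "group"))) {
    df <- df[-1L, , drop = FALSE]
  }
  sample_grouping(data.frame(sample_id = trimws(as.character(df$sample_id)),
                             group = trimws(as.character(df$group)),
                             stringsAsFactors = FALSE))
}

#' Construct/validate a sample grouping
#' @param df data frame with columns `sample_id`, `group`.
#' @return The validated grouping with class `sample_grouping`.
#' @export
sample_grouping <- function(df) {
  stopifnot(is.data.frame(df), all(c("sample_id", "group") %in% names(df)))
  if (anyDuplicated(df$sample_id)) {
    scdr_abort(paste0("sample(s) assigned more than once: ",
                      oxford_head(unique(df$sample_id[duplicated(df$sample_id)]))))
  }
  rownames(df) <- NULL
  class(df) <- c("sample_grouping", "data.frame")
  df
}

#' Write a sample grouping
#' @param grouping a `sample_grouping`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_sample_grouping <- function(grouping, path) {
  data.table::fwrite(as.data.frame(grouping), path, sep = "\t")
  invisible(path)
}

# ---- signature and DRS table serialization (long TSV: drug, gene, log2fc) ----

#' Write drug signatures to a long-format TSV
#' @param signatures a named list of [drug_signature()] objects.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_signatures <- function(signatures, path) {
  rows <- lapply(signatures, function(s) {
    data.frame(drug = attr(s, "drug"), gene = s$gene, log2fc = s$log2fc,
               stringsAsFactors = FALSE)
  })
  data.table::fwrite(do.call(rbind, rows), path, sep = "\t")
  invisible(path)
}

#' Read drug signatures from a long-format TSV
#' @param path TSV with columns `drug`, `gene`, `log2fc`.
#' @return Named list of [drug_signature()] objects.
#' @export
read_signatures <- function(path) {
  df <- read_delim_checked(path, "\t")
  need <- c("drug", "gene", "log2fc")
  if (!all(need %in% names(df))) {
    scdr_abort(paste0("signature file must have columns ", paste(need, collapse = ", ")),
               "scdr_parse_error")
  }
  sigs <- lapply(split(df, df$drug), function(d) {
    drug_signature(d$drug[1L], d$gene, as.numeric(d$log2fc))
  })
  sigs[unique(df$drug)]
}

#' Write a DRS matrix (drugs x samples) to TSV
#' @param drs a `drs_matrix` from [score_all()] or [aggregate_mdrs()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_drs <- function(drs, path) {
  df <- data.frame(drug = rownames(drs$scores), drs$scores,
                   check.names = FALSE, stringsAsFactors = FALSE)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Read a DRS matrix from TSV
#' @param path TSV written by [write_drs()].
#' @return A `drs_matrix` (intersection sizes `q_used` are not persisted and
#'   come back as `NA`).
#' @export
read_drs <- function(path) {
  df <- read_delim_checked(path, "\t")
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  structure(list(scores = m,
                 q_used = stats::setNames(rep(NA_integer_, nrow(m)), rownames(m)),
                 skipped = character()),
            class = "drs_matrix")
}
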