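# Independent reference implementations used to cross-check the package's
# vectorized/optimized paths. Deliberately naive.

# DRS by explicit per-sample, per-gene loops over the raw expression matrix.
oracle_drs <- function(expr_values, sig_genes, sig_weights) {
  n <- ncol(expr_values)
  # gene-wise standardization, one gene at a time
  z <- expr_values
  keep <- rep(TRUE, nrow(z))
  for (i in seq_len(nrow(z))) {
    s <- stats::sd(expr_values[i, ])
    if (s == 0) { keep[i] <- FALSE; next }
    for (m in seq_len(n)) {
      z[i, m] <- (expr_values[i, m] - mean(expr_values[i, ])) / s
    }
  }
  z <- z[keep, , drop = FALSE]
  genes <- intersect(sig_genes, rownames(z))
  drs <- numeric(n)
  for (m in seq_len(n)) {
    acc <- 0
    for (g in genes) {
      acc <- acc + sig_weights[match(g, sig_genes)] * z[g, m]
    }
    drs[m] <- acc / length(genes)
  }
  names(drs) <- colnames(expr_values)
  drs
}

# One-sided (greater) rank-sum p-value by enumeration of every assignment
# of the pooled midranks to the first group.
oracle_exact_wilcoxon_p <- function(x, y) {
  m <- length(x)
  rk <- rank(c(x, y))
  w_obs <- sum(rk[seq_len(m)])
  w_all <- utils::combn(length(rk), m, FUN = function(idx) sum(rk[idx]))
  mean(w_all >= w_obs - 1e-9)
}

# Classical concordance index by explicit pair counting.
oracle_cindex <- function(true_auc, predicted) {
  nm <- intersect(names(true_auc), names(predicted))
  a <- true_auc[nm]; p <- predicted[nm]
  num <- den <- 0
  for (i in seq_along(a)) {
    for (j in seq_along(a)) {
      if (j <= i || a[i] == a[j]) next
      den <- den + 1
      if (p[i] == p[j]) num <- num + 0.5
      else if (sign(p[i] - p[j]) == sign(a[i] - a[j])) num <- num + 1
    }
  }
  num / den
}

# Small random expression matrix with named dims.
random_em <- function(n_genes, n_samples, seed) {
  set.seed(seed)
  m <- matrix(stats::rlnorm(n_genes * n_samples), n_genes, n_samples,
              dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                              sprintf("S%03d", seq_len(n_samples))))
  expression_matrix(m)
}
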