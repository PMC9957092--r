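# Accuracy framework: one-sided rank-sum separation tests, accuracy over
# drugs, threefold cross-validation with [0,1] rescaling, and the weighted
# probabilistic concordance index (WPCI) for method comparison.

#' One-sided Wilcoxon rank-sum separation test
#'
#' Tests whether resistant samples score stochastically higher than
#' sensitive ones (H1: resistant > sensitive by default). A significant
#' result (`p < alpha`) counts as an accurate prediction for the drug.
#'
#' When the number of distinct group assignments is small
#' (`choose(m + n, m) <= exact_limit`, which covers group sizes up to 8 vs
#' 8), the p-value is computed by exact enumeration of all assignments of
#' the pooled (mid)ranks — exact even under ties. Larger problems use the
#' normal approximation with tie correction and continuity correction.
#'
#' @param scores_r,scores_s numeric scores of the resistant and sensitive
#'   groups (both nonempty).
#' @param alpha significance level (default 0.05).
#' @param alternative `"greater"` (resistant higher, default) or `"less"`.
#' @param drug optional drug id carried into the result.
#' @param exact_limit maximum number of enumerated arrangements.
#' @return A `separation_result`: list with `drug`, `n_resistant`,
#'   `n_sensitive`, `statistic` (Mann-Whitney U for the resistant group),
#'   `p_value`, `accurate`, `alpha`.
#' @export
wilcoxon_separation <- function(scores_r, scores_s, alpha = 0.05,
                                alternative = c("greater", "less"),
                                drug = NA_character_, exact_limit = 20000) {
  alternative <- match.arg(alternative)
  if (!length(scores_r) || !length(scores_s)) {
    scdr_abort("both score groups must be nonempty")
  }
  m <- length(scores_r)
  n <- length(scores_s)
  pooled <- c(scores_r, scores_s)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  if (choose(m + n, m) <= exact_limit) {
    sums <- colSums(matrix(r[utils::combn(m + n, m)], nrow = m))
    u_perm <- sums - m * (m + 1) / 2
    p <- if (alternative == "greater") {
      mean(u_perm >= u_obs - 1e-9)
    } else {
      mean(u_perm <= u_obs + 1e-9)
    }
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(scores_r, scores_s, alternative = alternative,
                         exact = FALSE, correct = TRUE)$p.value
    )
  }
  structure(list(drug = drug, n_resistant = m, n_sensitive = n,
                 statistic = u_obs, p_value = p, accurate = p < alpha,
                 alpha = alpha),
            class = "separation_result")
}

#' @export
print.separation_result <- function(x, ...) {
  cat(sprintf("<separation_result>%s U = %g, p = %.4g (%d R vs %d S) -> %s\n",
              if (is.na(x$drug)) "" else paste0(" drug ", x$drug, ":"),
              x$statistic, x$p_value, x$n_resistant, x$n_sensitive,
              if (x$accurate) "accurate" else "not accurate"))
  invisible(x)
}

#' Fraction of drugs predicted accurately
#'
#' @param results list of `separation_result` objects (or a data frame with
#'   a logical `accurate` column).
#' @return The fraction with `accurate = TRUE`.
#' @export
accuracy_over_drugs <- function(results) {
  if (is.data.frame(results)) {
    acc <- results$accurate
  } else {
    acc <- vapply(results, function(r) isTRUE(r$accurate), logical(1L))
  }
  if (!length(acc)) scdr_abort("no separation results supplied")
  mean(acc)
}

#' Rescale values linearly into [0, 1]
#'
#' `(v - min) / (max - min)`; a constant vector maps to all 0.5. Used to put
#' cross-validation test scores from different folds on a common scale.
#'
#' @param values numeric vector (length >= 2).
#' @return Rescaled vector with the same names and rank order.
#' @export
min_max_rescale <- function(values) {
  if (length(values) < 2L) scdr_abort("need at least two values to rescale")
  rng <- range(values)
  if (rng[1] == rng[2]) {
    out <- rep(0.5, length(values))
    names(out) <- names(values)
    return(out)
  }
  (values - rng[1]) / (rng[2] - rng[1])
}

#' Threefold cross-validation of signature-based separation
#'
#' For each permutation, the resistant and sensitive training lines are
#' independently shuffled and split into `folds` near-equal groups. Each
#' fold pairs one resistant group with one sensitive group as the test set;
#' the remaining lines form the training set, on which the signature is
#' re-derived. Test-set samples are scored, the scores are min-max rescaled
#' into [0, 1] within the test, and a one-sided rank-sum test asks whether
#' held-out resistant lines score higher. Each fold of each permutation is
#' one test (3 folds x 100 permutations = 900 tests at the defaults).
#'
#' Tests whose training or scoring step fails (e.g. a fold losing all genes)
#' are marked invalid and excluded from the accuracy denominator; the count
#' is reported in the result.
#'
#' @param expr linear-scale training [expression_matrix()].
#' @param labels `response_labels` for one drug; both sides need at least
#'   `folds` members.
#' @param folds number of folds (default 3).
#' @param permutations number of independent reshuffles (default 100).
#' @param seed RNG seed; the report is reproducible given the seed.
#' @param n_top,pseudocount passed to [derive_signature()].
#' @param alpha significance level per test.
#' @return A `cv_report`: list with `drug`, `n_tests`, `n_invalid`,
#'   `per_test` (data frame: `fold`, `permutation`, `p_value`, `valid`),
#'   and `accuracy_fraction` over valid tests.
#' @export
cross_validate <- function(expr, labels, folds = 3L, permutations = 100L,
                           seed = 1L, n_top = 200L, pseudocount = 0.01,
                           alpha = 0.05) {
  r_all <- intersect(labels$resistant, sample_ids(expr))
  s_all <- intersect(labels$sensitive, sample_ids(expr))
  if (length(r_all) < folds || length(s_all) < folds) {
    scdr_abort(sprintf("drug '%s': need >= %d lines per side for %d-fold CV (have %d R, %d S)",
                       labels$drug, folds, folds, length(r_all), length(s_all)))
  }
  per_test <- with_seed(seed, {
    out <- vector("list", folds * permutations)
    k <- 0L
    for (perm in seq_len(permutations)) {
      r_perm <- sample(r_all)
      s_perm <- sample(s_all)
      f_r <- rep_len(seq_len(folds), length(r_perm))
      f_s <- rep_len(seq_len(folds), length(s_perm))
      for (f in seq_len(folds)) {
        test_r <- r_perm[f_r == f]
        test_s <- s_perm[f_s == f]
        train_lab <- response_labels(labels$drug,
                                     resistant = r_perm[f_r != f],
                                     sensitive = s_perm[f_s != f])
        p <- tryCatch({
          sig <- derive_signature(expr, train_lab, n_top = n_top,
                                  pseudocount = pseudocount)
          z <- suppressMessages(zscore_transform(em_subset(expr, samples = c(test_r, test_s))))
          row <- score_samples(z, sig)
          sc <- min_max_rescale(row$scores)
          wilcoxon_separation(sc[test_r], sc[test_s], alpha = alpha)$p_value
        }, error = function(e) NA_real_)
        k <- k + 1L
        out[[k]] <- data.frame(fold = f, permutation = perm, p_value = p,
                               valid = is.finite(p))
      }
    }
    do.call(rbind, out)
  })
  valid <- per_test$valid
  structure(list(drug = labels$drug,
                 n_tests = sum(valid),
                 n_invalid = sum(!valid),
                 per_test = per_test,
                 accuracy_fraction = mean(per_test$p_value[valid] < alpha),
                 alpha = alpha, folds = folds, permutations = permutations,
                 seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> drug %s: accuracy %.2f%% over %d valid tests (%d invalid; %d folds x %d permutations, seed %d)\n",
              x$drug, 100 * x$accuracy_fraction, x$n_tests, x$n_invalid,
              x$folds, x$permutations, x$seed))
  invisible(x)
}

#' Weighted probabilistic concordance index
#'
#' A concordance index between true AUC values and predicted scores in which
#' each discordant-or-concordant line pair is weighted by the probability
#' that its true AUC ordering is real given Gaussian measurement noise:
#' `w_ij = pnorm(|AUC_i - AUC_j| / (noise_sd * sqrt(2)))`. A pair counts 1
#' when the predictions order it as the AUCs do, 0.5 when the predictions
#' tie, and 0 otherwise; pairs with equal AUC are excluded. The returned
#' index is `sum(w * credit) / sum(w)`, in [0, 1], with 0.5 the chance
#' level. Absolute values depend on `noise_sd`, but rankings of competing
#' methods are stable under it; it is invariant to any strictly increasing
#' transform of the predictions.
#'
#' @param true_auc named numeric vector of true AUC per cell line.
#' @param predicted named numeric vector of predicted scores; only lines
#'   shared with `true_auc` are used (>= 2 required, with >= 2 distinct AUC
#'   values).
#' @param noise_sd assumed AUC measurement noise sd (> 0); defaults to 10%
#'   of the sample sd of the shared true AUC values.
#' @param unit_weights set `TRUE` to force all pair weights to 1, reducing
#'   the index to the classical concordance index.
#' @param drug optional drug id carried into the result.
#' @return A `wpci_result`: list with `drug`, `wpci`, `n_pairs_weighted`
#'   (sum of weights), and `noise_sd`.
#' @export
wpci <- function(true_auc, predicted, noise_sd = NULL, unit_weights = FALSE,
                 drug = NA_character_) {
  shared <- intersect(names(true_auc), names(predicted))
  if (length(shared) < 2L) scdr_abort("need at least two shared cell lines")
  a <- true_auc[shared]
  p <- predicted[shared]
  if (length(unique(a)) < 2L) scdr_abort("need at least two distinct AUC values")
  if (is.null(noise_sd)) noise_sd <- 0.1 * stats::sd(a)
  if (!is.finite(noise_sd) || noise_sd <= 0) scdr_abort("noise_sd must be positive")
  da <- outer(a, a, `-`)
  dp <- outer(p, p, `-`)
  sel <- upper.tri(da) & da != 0
  w <- if (unit_weights) rep(1, sum(sel)) else stats::pnorm(abs(da[sel]) / (noise_sd * sqrt(2)))
  credit <- ifelse(dp[sel] == 0, 0.5, as.numeric(sign(dp[sel]) == sign(da[sel])))
  structure(list(drug = drug, wpci = sum(w * credit) / sum(w),
                 n_pairs_weighted = sum(w), noise_sd = noise_sd),
            class = "wpci_result")
}

#' Compare two prediction methods by per-drug WPCI
#'
#' Computes the WPCI of both methods for every drug, counts the drugs where
#' method A outranks method B, and tests the paired per-drug WPCIs with a
#' one-sided Wilcoxon signed-rank test (H1: A > B).
#'
#' @param true_auc named list (per drug) of named AUC vectors per line.
#' @param method_a,method_b named lists (same drugs) of predicted score
#'   vectors per line.
#' @param noise_sd,unit_weights passed to [wpci()].
#' @return List with `per_drug` (data frame: `drug`, `wpci_a`, `wpci_b`),
#'   `n_a_higher`, `fraction_a_higher`, and `p_value`.
#' @export
compare_methods <- function(true_auc, method_a, method_b, noise_sd = NULL,
                            unit_weights = FALSE) {
  drugs <- names(true_auc)
  if (!setequal(drugs, names(method_a)) || !setequal(drugs, names(method_b))) {
    scdr_abort("the two methods and the truth must cover the same drugs")
  }
  wa <- vapply(drugs, function(d) wpci(true_auc[[d]], method_a[[d]],
                                       noise_sd = noise_sd,
                                       unit_weights = unit_weights)$wpci, numeric(1L))
  wb <- vapply(drugs, function(d) wpci(true_auc[[d]], method_b[[d]],
                                       noise_sd = noise_sd,
                                       unit_weights = unit_weights)$wpci, numeric(1L))
  d <- wa - wb
  p <- if (all(d == 0)) 1 else suppressWarnings(
    stats::wilcox.test(wa, wb, paired = TRUE, alternative = "greater",
                       exact = FALSE, correct = TRUE)$p.value
  )
  list(per_drug = data.frame(drug = drugs, wpci_a = wa, wpci_b = wb,
                             row.names = NULL, stringsAsFactors = FALSE),
       n_a_higher = sum(d > 0),
       fraction_a_higher = mean(d > 0),
       p_value = p)
}

#' Per-drug DRS comparison between two externally defined sample groups
#'
#' For every drug in a DRS matrix, runs a one-sided rank-sum test of
#' H1: group A scores higher than group B (e.g. two clusters of untreated
#' cells, to detect an intrinsically resistant subpopulation).
#'
#' @param drs a `drs_matrix`.
#' @param grouping a [sample_grouping()] over the scored samples.
#' @param group_a,group_b group labels present in `grouping`.
#' @param alpha significance level.
#' @param adjust_p also report Benjamini-Hochberg adjusted p-values
#'   (default `FALSE`; the `accurate` call always uses the raw p).
#' @return Data frame with one row per drug: `drug`, `n_a`, `n_b`,
#'   `statistic`, `p_value`, `accurate` (and `p_adjusted` if requested).
#' @export
group_drs_comparison <- function(drs, grouping, group_a, group_b,
                                 alpha = 0.05, adjust_p = FALSE) {
  for (g in c(group_a, group_b)) {
    if (!g %in% grouping$group) scdr_abort(paste0("unknown group label: ", g))
  }
  cells <- colnames(drs$scores)
  a_cells <- intersect(cells, grouping$sample_id[grouping$group == group_a])
  b_cells <- intersect(cells, grouping$sample_id[grouping$group == group_b])
  if (!length(a_cells) || !length(b_cells)) {
    scdr_abort("both groups must contain scored samples")
  }
  rows <- lapply(rownames(drs$scores), function(d) {
    r <- wilcoxon_separation(drs$scores[d, a_cells], drs$scores[d, b_cells],
                             alpha = alpha, drug = d)
    data.frame(drug = d, n_a = r$n_resistant, n_b = r$n_sensitive,
               statistic = r$statistic, p_value = r$p_value,
               accurate = r$accurate, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (adjust_p) out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out
}
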