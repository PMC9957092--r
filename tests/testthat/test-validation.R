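# Separation tests, cross-validation, and concordance-based comparison.

test_that("rank-sum separation matches exact enumeration in the extreme case", {
  r <- wilcoxon_separation(c(4, 5, 6), c(1, 2, 3))
  expect_equal(r$p_value, 0.05, tolerance = 1e-12)   # 1 of choose(6,3) = 20
  expect_false(r$accurate)                            # strict p < alpha
  swapped <- wilcoxon_separation(c(1, 2, 3), c(4, 5, 6))
  expect_gte(swapped$p_value, 0.95)
  expect_false(swapped$accurate)
  expect_equal(wilcoxon_separation(2, 1)$p_value, 0.5)  # minimal enumeration
  expect_error(wilcoxon_separation(numeric(0), 1), "nonempty")
})

test_that("exact path agrees with enumeration and wilcox.test for sizes <= 8", {
  set.seed(81)
  for (rep in 1:20) {
    m <- sample(1:8, 1); n <- sample(1:8, 1)
    x <- rnorm(m); y <- rnorm(n)
    got <- wilcoxon_separation(x, y)$p_value
    expect_equal(got, oracle_exact_wilcoxon_p(x, y), tolerance = 1e-9)
    expect_equal(got, wilcox.test(x, y, alternative = "greater",
                                  exact = TRUE)$p.value, tolerance = 1e-9)
    # tied data: enumeration over midranks is still the reference
    xt <- sample(1:3, m, replace = TRUE); yt <- sample(1:3, n, replace = TRUE)
    expect_equal(wilcoxon_separation(xt, yt)$p_value,
                 oracle_exact_wilcoxon_p(xt, yt), tolerance = 1e-9)
  }
})

test_that("type-I error of the approximate path is near alpha", {
  set.seed(82)
  hits <- replicate(400, wilcoxon_separation(rnorm(20), rnorm(20))$accurate)
  ci <- qbinom(c(0.005, 0.995), 400, 0.05) / 400
  expect_gte(mean(hits), ci[1])
  expect_lte(mean(hits), ci[2])
})

test_that("accuracy over drugs is the fraction of significant separations", {
  mk <- function(p) structure(list(drug = "d", p_value = p, accurate = p < 0.05),
                              class = "separation_result")
  expect_equal(accuracy_over_drugs(list(mk(0.01), mk(0.2), mk(0.04), mk(0.5))), 0.5)
  expect_equal(accuracy_over_drugs(list(mk(0.01))), 1)
  expect_equal(accuracy_over_drugs(list(mk(0.99))), 0)
})

test_that("min-max rescaling is the linear map with the constant-vector rule", {
  expect_equal(min_max_rescale(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(min_max_rescale(c(7, 7, 7)), rep(0.5, 3))
  set.seed(83)
  v <- rnorm(30)
  expect_identical(rank(min_max_rescale(v)), rank(v))
  expect_error(min_max_rescale(1), "two values")
})

test_that("cross-validation separates a planted drug and is seed-reproducible", {
  cfg <- sim_config(n_genes = 800, n_signature_up = 100, n_signature_down = 100,
                    n_resistant = 12, n_sensitive = 12, n_intermediate = 0,
                    effect_log2fc = 1, seed = 84)
  bulk <- simulate_bulk_cohort(cfg)
  lab <- bulk$truth$line_labels$D01
  rl <- response_labels("D01", names(lab)[lab == "R"], names(lab)[lab == "S"])
  cv <- cross_validate(bulk$expr, rl, folds = 3, permutations = 3, seed = 7,
                       n_top = 100)
  expect_identical(cv$n_tests + cv$n_invalid, 9L)
  expect_gte(cv$accuracy_fraction, 0.9)
  cv2 <- cross_validate(bulk$expr, rl, folds = 3, permutations = 3, seed = 7,
                        n_top = 100)
  expect_identical(cv$per_test, cv2$per_test)
  expect_error(cross_validate(bulk$expr, response_labels("D01", c("L001", "L002"),
                                                         c("L003", "L004")),
                              folds = 3),
               "need >= 3 lines per side")
})

test_that("cross-validation accuracy is near alpha under permuted labels", {
  cfg <- sim_config(n_genes = 400, n_signature_up = 50, n_signature_down = 50,
                    n_resistant = 12, n_sensitive = 12, n_intermediate = 0,
                    effect_log2fc = 1, seed = 85)
  bulk <- simulate_bulk_cohort(cfg)
  lines <- sample_ids(bulk$expr)
  set.seed(86)
  shuffled <- sample(lines)
  rl <- response_labels("D01", shuffled[1:12], shuffled[13:24])
  cv <- cross_validate(bulk$expr, rl, folds = 3, permutations = 100, seed = 9,
                       n_top = 50)
  ci <- qbinom(c(0.005, 0.995), cv$n_tests, 0.05) / cv$n_tests
  expect_gte(cv$accuracy_fraction, ci[1])
  expect_lte(cv$accuracy_fraction, ci[2])
})

test_that("WPCI hits its boundary values and reduces to the c-index", {
  set.seed(87)
  auc <- setNames(runif(30, 5, 15), sprintf("L%02d", 1:30))
  expect_equal(wpci(auc, auc)$wpci, 1)
  expect_equal(wpci(auc, -auc)$wpci, 0)
  for (rep in 1:5) {
    pred <- setNames(rnorm(30), names(auc))
    got <- wpci(auc, pred, unit_weights = TRUE)$wpci
    expect_equal(got, oracle_cindex(auc, pred), tolerance = 1e-12)
  }
  expect_error(wpci(setNames(c(1, 1), c("a", "b")), setNames(c(1, 2), c("a", "b"))),
               "distinct AUC")
  expect_error(wpci(setNames(1, "a"), setNames(1, "b")), "shared cell lines")
})

test_that("WPCI is invariant under strictly increasing prediction transforms", {
  set.seed(88)
  auc <- setNames(rnorm(25, 10), sprintf("L%02d", 1:25))
  pred <- setNames(rnorm(25), names(auc))
  base <- wpci(auc, pred)$wpci
  expect_equal(wpci(auc, exp(pred))$wpci, base)
  expect_equal(wpci(auc, rank(pred))$wpci, base)
})

test_that("method comparison counts per-drug WPCI wins and self-compares to p = 1", {
  set.seed(89)
  lines <- sprintf("L%02d", 1:20)
  truth <- lapply(1:6, function(i) setNames(rnorm(20, 10), lines))
  names(truth) <- paste0("d", 1:6)
  good <- lapply(truth, function(a) a + rnorm(20, sd = 0.2))  # tracks the AUC
  bad <- lapply(good, function(p) -p)                          # rank reversal
  self <- compare_methods(truth, good, good)
  expect_equal(self$fraction_a_higher, 0)
  expect_equal(self$p_value, 1)
  cmp <- compare_methods(truth, good, bad)
  expect_equal(cmp$fraction_a_higher, 1)
  expect_lt(cmp$p_value, 0.05)
  expect_error(compare_methods(truth, good[1:5], bad), "same drugs")
})

test_that("group comparison separates planted clusters and handles edge cases", {
  set.seed(90)
  scores <- rbind(dA = c(rnorm(20, 3), rnorm(20, 0)),
                  dB = rnorm(40))
  colnames(scores) <- paste0("c", 1:40)
  drs <- structure(list(scores = scores, q_used = c(dA = 5L, dB = 5L),
                        skipped = character()), class = "drs_matrix")
  grouping <- sample_grouping(data.frame(sample_id = paste0("c", 1:40),
                                         group = rep(c("d0-R", "d0-S"), each = 20)))
  rep <- group_drs_comparison(drs, grouping, "d0-R", "d0-S", adjust_p = TRUE)
  expect_lt(rep$p_value[rep$drug == "dA"], 1e-6)
  expect_true(all(c("p_adjusted") %in% names(rep)))
  expect_error(group_drs_comparison(drs, grouping, "d0-R", "missing"),
               "unknown group label")
})
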