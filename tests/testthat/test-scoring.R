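# Z-transform and fold-change-weighted scoring.

test_that("z-scores match hand arithmetic and standardization identities", {
  m <- rbind(G1 = c(1, 3), G2 = c(5, 5))
  colnames(m) <- c("s1", "s2")
  z <- suppressMessages(zscore_transform(expression_matrix(m)))
  expect_equal(unname(z$values["G1", ]), c(-1, 1) / sqrt(2), tolerance = 1e-12)
  expect_identical(z$dropped_genes, "G2")      # constant gene absent

  em <- random_em(80, 15, seed = 51)
  z2 <- zscore_transform(em)
  expect_lt(max(abs(rowMeans(z2$values))), 1e-8)
  sds <- apply(z2$values, 1, sd)
  expect_lt(max(abs(sds - 1)), 1e-6)
})

test_that("a single-sample matrix cannot be standardized", {
  m <- matrix(1:3, 3, 1, dimnames = list(paste0("G", 1:3), "s1"))
  expect_error(zscore_transform(expression_matrix(m)), "two samples")
})

test_that("sparse batched standardization equals the dense computation", {
  set.seed(52)
  m <- matrix(rpois(300 * 20, 2), 300, 20,
              dimnames = list(sprintf("G%03d", 1:300), sprintf("c%02d", 1:20)))
  dense <- suppressMessages(zscore_transform(expression_matrix(m)))
  sparse <- suppressMessages(zscore_transform(
    expression_matrix(Matrix::Matrix(m, sparse = TRUE)), batch_rows = 7L))
  expect_equal(sparse$values, dense$values, tolerance = 1e-12)
})

test_that("scoring closed forms: q = 1 passthrough and exact cancellation", {
  z <- structure(list(values = rbind(G1 = c(a = 2, b = -2)),
                      dropped_genes = character()), class = "zscore_matrix")
  sig <- drug_signature("d", "G1", 1)
  expect_equal(score_samples(z, sig)$scores, c(a = 2, b = -2))

  z2 <- structure(list(values = rbind(G1 = c(a = 0.5), G2 = c(a = 0.5)),
                       dropped_genes = character()), class = "zscore_matrix")
  sig2 <- drug_signature("d", c("G1", "G2"), c(1, -1))
  expect_equal(unname(score_samples(z2, sig2)$scores), 0)
})

test_that("vectorized DRS equals the naive triple-loop oracle", {
  for (seed in c(61, 62, 63)) {
    em <- random_em(100, 20, seed = seed)
    set.seed(seed + 1000)
    sig_genes <- sample(gene_ids(em), 50)
    weights <- round(rnorm(50), 3)
    weights[weights == 0] <- 0.5
    sig <- drug_signature("d", sig_genes, weights)
    z <- zscore_transform(em)
    got <- score_samples(z, sig)$scores
    want <- oracle_drs(as.matrix(em), sig_genes, weights)
    expect_equal(got, want, tolerance = 1e-10)
    expect_equal(score_samples(z, sig)$q_used, 50L)
  }
})

test_that("score_all factorizes over drugs and is column-equivariant", {
  em <- random_em(60, 12, seed = 64)
  set.seed(65)
  sigs <- list(drug_signature("dA", sample(gene_ids(em), 10), rnorm(10) + 2),
               drug_signature("dB", sample(gene_ids(em), 8), -(rnorm(8) + 2)),
               drug_signature("dC", paste0("X", 1:4), rep(1, 4)))  # absent genes
  drs <- suppressMessages(score_all(em, sigs))
  expect_identical(rownames(drs$scores), c("dA", "dB"))
  expect_identical(drs$skipped, "dC")
  z <- zscore_transform(em)
  expect_equal(drs$scores["dA", ], score_samples(z, sigs[[1]])$scores)

  perm <- sample(ncol(em$values))
  em_p <- expression_matrix(em$values[, perm])
  drs_p <- suppressMessages(score_all(em_p, sigs))
  expect_equal(drs_p$scores, drs$scores[, perm])
})

test_that("all drugs missing from the profile is an error", {
  em <- random_em(10, 4, seed = 66)
  sig <- drug_signature("d", c("nope1", "nope2"), c(1, -1))
  expect_error(score_all(em, list(sig)), "every drug was skipped")
  expect_error(score_samples(zscore_transform(em), sig), "no signature genes")
})

test_that("negating the signature negates every score exactly", {
  em <- random_em(50, 10, seed = 67)
  set.seed(68)
  genes <- sample(gene_ids(em), 20)
  w <- rnorm(20) + 1
  z <- zscore_transform(em)
  s_pos <- score_samples(z, drug_signature("d", genes, w))$scores
  s_neg <- score_samples(z, drug_signature("d", genes, -w))$scores
  expect_identical(s_pos, -s_neg)
})

test_that("gene-wise positive affine transforms leave DRS unchanged", {
  em <- random_em(50, 10, seed = 69)
  set.seed(70)
  genes <- sample(gene_ids(em), 20)
  sig <- drug_signature("d", genes, rnorm(20) + 1)
  base <- score_samples(zscore_transform(em), sig)$scores
  a <- runif(50, 0.2, 5)
  b <- rnorm(50, sd = 10)
  shifted <- expression_matrix(em$values * a + b, is_log_scale = TRUE)
  moved <- score_samples(zscore_transform(shifted), sig)$scores
  expect_equal(moved, base, tolerance = 1e-8)
})

test_that("mDRS aggregation is the per-line mean and respects the grand mean", {
  scores <- rbind(dA = c(1, 3, 5, 7, 2), dB = c(0, 2, -2, 4, 6))
  colnames(scores) <- paste0("c", 1:5)
  drs <- structure(list(scores = scores, q_used = c(dA = 3L, dB = 3L),
                        skipped = character()), class = "drs_matrix")
  map <- sample_grouping(data.frame(sample_id = paste0("c", 1:5),
                                    group = c("L1", "L1", "L2", "L3", "L3")))
  agg <- aggregate_mdrs(drs, map)
  expect_equal(agg$scores["dA", ], c(L1 = 2, L2 = 5, L3 = 4.5))
  counts <- c(L1 = 2, L2 = 1, L3 = 2)
  expect_equal(sum(agg$scores["dB", ] * counts) / sum(counts),
               mean(scores["dB", ]))
  map_short <- sample_grouping(data.frame(sample_id = paste0("c", 1:4),
                                          group = c("L1", "L1", "L2", "L3")))
  expect_error(aggregate_mdrs(drs, map_short), "missing from the cell-to-line map")
})

test_that("mean DRS over scored samples is zero for every drug", {
  for (seed in 71:75) {
    cfg <- sim_config(n_genes = 120, n_signature_up = 15, n_signature_down = 15,
                      n_resistant = 6, n_sensitive = 6, n_intermediate = 3,
                      n_drugs = 2, seed = seed)
    bulk <- simulate_bulk_cohort(cfg)
    sigs <- suppressMessages(derive_all_signatures(bulk$expr, bulk$response,
                                                   n_top = 15, min_group_size = 1))
    drs <- suppressMessages(score_all(bulk$expr, sigs))
    expect_lt(max(abs(rowMeans(drs$scores))), 1e-8)
  }
})
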