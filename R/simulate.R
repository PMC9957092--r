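# Seeded synthetic pharmacogenomic cohorts: bulk expression with planted
# drug-response genes, AUC values coupled to planted signature activity,
# and overdispersed single-cell counts with dropout.

#' Simulation configuration
#'
#' Bundles and validates every knob of the synthetic cohort generator.
#' Defaults describe a discovery-style bulk cohort: 2000 genes with a
#' 200-up / 200-down planted signature per drug, 30 resistant + 30
#' sensitive + 30 intermediate cell lines, a one-unit log2 expression shift
#' between resistant and sensitive lines for planted genes, moderate
#' line-to-line noise, and AUC values partially coupled to the planted
#' signal.
#'
#' @param n_genes total genes.
#' @param n_signature_up,n_signature_down planted up/down genes per drug
#'   (`n_drugs * (up + down) <= n_genes`; planted sets are disjoint).
#' @param n_resistant,n_sensitive,n_intermediate cell lines per truth class.
#' @param n_drugs independent drugs sharing the expression matrix.
#' @param effect_log2fc planted log2 fold change between resistant and
#'   sensitive lines (>= 0; split symmetrically, +/- half per side, with
#'   intermediate lines at baseline).
#' @param noise_sd natural-log-scale sd of multiplicative expression noise.
#' @param auc_coupling in [0, 1]: weight of planted signature activity in
#'   the AUC (0 = AUC is pure noise, 1 = AUC is a deterministic function of
#'   realized expression).
#' @param seed RNG seed; everything downstream is reproducible from it.
#' @param single_cell logical: config intended for [simulate_single_cell()].
#' @param cells_per_line cells simulated per cell line.
#' @param dropout_rate Bernoulli zeroing probability per count (in [0, 1)).
#' @param nb_dispersion negative-binomial size parameter (> 0; larger is
#'   closer to Poisson).
#' @param mean_library_size mean per-cell total count.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_genes = 2000L, n_signature_up = 200L,
                       n_signature_down = 200L, n_resistant = 30L,
                       n_sensitive = 30L, n_intermediate = 30L,
                       n_drugs = 1L, effect_log2fc = 1, noise_sd = 0.25,
                       auc_coupling = 0.7, seed = 1L, single_cell = FALSE,
                       cells_per_line = 100L, dropout_rate = 0.3,
                       nb_dispersion = 2, mean_library_size = 20000) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_signature_up = as.integer(n_signature_up),
              n_signature_down = as.integer(n_signature_down),
              n_resistant = as.integer(n_resistant),
              n_sensitive = as.integer(n_sensitive),
              n_intermediate = as.integer(n_intermediate),
              n_drugs = as.integer(n_drugs),
              effect_log2fc = effect_log2fc, noise_sd = noise_sd,
              auc_coupling = auc_coupling, seed = as.integer(seed),
              single_cell = isTRUE(single_cell),
              cells_per_line = as.integer(cells_per_line),
              dropout_rate = dropout_rate, nb_dispersion = nb_dispersion,
              mean_library_size = mean_library_size)
  if (cfg$n_drugs * (cfg$n_signature_up + cfg$n_signature_down) > cfg$n_genes) {
    scdr_abort("planted signature genes across drugs exceed n_genes")
  }
  if (cfg$effect_log2fc < 0) scdr_abort("effect_log2fc must be >= 0")
  if (cfg$effect_log2fc > 0 && (cfg$n_resistant == 0L || cfg$n_sensitive == 0L)) {
    scdr_abort("a nonzero effect needs at least one resistant and one sensitive line")
  }
  if (cfg$auc_coupling < 0 || cfg$auc_coupling > 1) scdr_abort("auc_coupling must be in [0, 1]")
  if (cfg$dropout_rate < 0 || cfg$dropout_rate >= 1) scdr_abort("dropout_rate must be in [0, 1)")
  if (cfg$nb_dispersion <= 0) scdr_abort("nb_dispersion must be > 0")
  if (cfg$noise_sd < 0) scdr_abort("noise_sd must be >= 0")
  structure(cfg, class = "sim_config")
}

#' Simulate a bulk pharmacogenomic cohort with planted signatures
#'
#' Generates a linear-scale expression matrix and a matched AUC table.
#' Baseline expression is log-normal per gene. For every drug, a disjoint
#' block of planted up-genes is shifted `+effect/2` log2 units in that
#' drug's resistant lines and `-effect/2` in its sensitive lines (planted
#' down-genes mirrored), so the realized resistant-vs-sensitive log2 fold
#' change of a planted gene is `effect_log2fc`; intermediate lines sit at
#' baseline, exercising the unlabelled middle band of the AUC rule.
#' Multiplicative log-normal noise (`noise_sd`) is applied everywhere.
#'
#' Each drug's true activity per line is the signed mean of its planted
#' genes' standardized log2 expression; the AUC mixes the standardized
#' activity with standard-normal noise at weight `auc_coupling` and is then
#' affine-mapped to an arbitrary positive range (downstream labelling is
#' affine-invariant, so the range is cosmetic).
#'
#' @param config a [sim_config()].
#' @return List with `expr` (linear [expression_matrix()]), `response`
#'   (a [drug_response_table()]), and `truth` (`synthetic_truth`: per-drug
#'   `planted_up`, `planted_down`, `line_labels`, `true_activity`).
#' @export
simulate_bulk_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n_lines <- config$n_resistant + config$n_sensitive + config$n_intermediate
    if (n_lines < 2L) scdr_abort("need at least two cell lines")
    lines <- sprintf("L%03d", seq_len(n_lines))
    genes <- sprintf("G%04d", seq_len(config$n_genes))
    drugs <- sprintf("D%02d", seq_len(config$n_drugs))

    gene_pool <- sample(genes)
    block <- config$n_signature_up + config$n_signature_down
    planted_up <- planted_down <- line_labels <- true_activity <- list()

    offsets <- matrix(0, config$n_genes, n_lines, dimnames = list(genes, lines))
    for (i in seq_along(drugs)) {
      d <- drugs[i]
      slice <- gene_pool[seq.int((i - 1L) * block + 1L, i * block)]
      planted_up[[d]] <- sort(slice[seq_len(config$n_signature_up)])
      planted_down[[d]] <- sort(slice[seq.int(config$n_signature_up + 1L, block)])
      shuffled <- sample(lines)
      lab <- rep("intermediate", n_lines)
      names(lab) <- shuffled
      lab[seq_len(config$n_resistant)] <- "R"
      lab[seq.int(config$n_resistant + 1L, config$n_resistant + config$n_sensitive)] <- "S"
      lab <- lab[lines]
      line_labels[[d]] <- lab
      half <- config$effect_log2fc / 2
      offsets[planted_up[[d]], lab == "R"] <- offsets[planted_up[[d]], lab == "R"] + half
      offsets[planted_up[[d]], lab == "S"] <- offsets[planted_up[[d]], lab == "S"] - half
      offsets[planted_down[[d]], lab == "R"] <- offsets[planted_down[[d]], lab == "R"] - half
      offsets[planted_down[[d]], lab == "S"] <- offsets[planted_down[[d]], lab == "S"] + half
    }

    baseline <- stats::rlnorm(config$n_genes, meanlog = log(20), sdlog = 1)
    noise <- matrix(exp(stats::rnorm(config$n_genes * n_lines, sd = config$noise_sd)),
                    config$n_genes, n_lines)
    values <- baseline * 2^offsets * noise
    dimnames(values) <- list(genes, lines)

    records <- vector("list", length(drugs))
    for (i in seq_along(drugs)) {
      d <- drugs[i]
      lv <- log2(values[c(planted_up[[d]], planted_down[[d]]), , drop = FALSE])
      zz <- (lv - rowMeans(lv)) / apply(lv, 1L, stats::sd)
      sgn <- c(rep(1, length(planted_up[[d]])), rep(-1, length(planted_down[[d]])))
      act <- colMeans(zz * sgn)
      true_activity[[d]] <- act
      raw <- config$auc_coupling * as.vector(scale(act)) +
        (1 - config$auc_coupling) * stats::rnorm(n_lines)
      records[[i]] <- data.frame(cell_line = lines, drug = d, auc = 10 + 2 * raw,
                                 stringsAsFactors = FALSE)
    }

    list(expr = expression_matrix(values, is_log_scale = FALSE),
         response = drug_response_table(do.call(rbind, records)),
         truth = structure(list(planted_up = planted_up,
                                planted_down = planted_down,
                                line_labels = line_labels,
                                true_activity = true_activity),
                           class = "synthetic_truth"))
  })
}

#' Simulate single-cell counts for a bulk cohort's cell lines
#'
#' Draws `cells_per_line` cells per line. Each cell's library size is
#' log-normal around `mean_library_size`; per-gene means follow the line's
#' bulk expression profile scaled to that library; counts are negative-
#' binomial with size `nb_dispersion`, then thinned by Bernoulli dropout.
#'
#' @param config a [sim_config()] with `single_cell = TRUE`.
#' @param bulk result of [simulate_bulk_cohort()] (line profiles + truth).
#' @return List with `counts` (sparse raw-count [expression_matrix()],
#'   cells as columns) and `cell_to_line` (a [sample_grouping()]).
#' @export
simulate_single_cell <- function(config, bulk) {
  stopifnot(inherits(config, "sim_config"))
  if (!config$single_cell) scdr_abort("config does not have single_cell = TRUE")
  profile <- as.matrix(bulk$expr$values)
  lines <- colnames(profile)
  with_seed(config$seed + 499979L, {
    per_line <- vector("list", length(lines))
    cell_ids <- vector("list", length(lines))
    for (j in seq_along(lines)) {
      libs <- stats::rlnorm(config$cells_per_line,
                            meanlog = log(config$mean_library_size), sdlog = 0.3)
      p <- profile[, j] / sum(profile[, j])
      mu <- outer(p, libs)
      counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = config$nb_dispersion),
                       nrow = nrow(profile))
      if (config$dropout_rate > 0) {
        keep <- matrix(stats::rbinom(length(mu), 1L, 1 - config$dropout_rate),
                       nrow = nrow(profile))
        counts <- counts * keep
      }
      per_line[[j]] <- counts
      cell_ids[[j]] <- sprintf("%s_c%04d", lines[j], seq_len(config$cells_per_line))
    }
    m <- do.call(cbind, per_line)
    dimnames(m) <- list(rownames(profile), unlist(cell_ids))
    grouping <- sample_grouping(data.frame(
      sample_id = unlist(cell_ids),
      group = rep(lines, each = config$cells_per_line),
      stringsAsFactors = FALSE))
    list(counts = expression_matrix(Matrix::Matrix(m, sparse = TRUE),
                                    is_log_scale = FALSE),
         cell_to_line = grouping)
  })
}

#' Hand-checkable toy cohort
#'
#' A deterministic miniature cohort built from closed-form values: six genes
#' (two up, two down, two housekeeping) across six training lines (two
#' resistant, two middle-band, two sensitive) plus a three-sample profile to
#' score. Expected log2 fold changes, z-scores and DRS values are computed
#' by hand and returned alongside the data, so every arithmetic step of the
#' pipeline can be checked exactly.
#'
#' With `pseudocount = 0` and `n_top = 2`: gene UP1 has resistant mean 4 and
#' sensitive mean 1, so log2FC = 2; the scored samples T1..T3 have DRS
#' -1.5, 0, +1.5.
#'
#' @return List with `expr_train`, `response`, `expr_score`, the derivation
#'   settings (`n_top`, `pseudocount`), and `expected` (`log2fc`, `zscore`,
#'   `drs`).
#' @export
make_toy_fixture <- function() {
  train <- rbind(
    UP1 = c(4, 4, 2.5, 2.5, 1, 1),
    UP2 = c(3, 3, 2, 2, 1.5, 1.5),
    DN1 = c(1, 1, 2.5, 2.5, 4, 4),
    DN2 = c(2, 2, 3, 3, 4, 4),
    HK1 = c(2, 2, 2, 2, 2, 2),
    HK2 = c(5, 5, 5, 5, 5, 5))
  colnames(train) <- c("R1", "R2", "M1", "M2", "S1", "S2")
  response <- drug_response_table(data.frame(
    cell_line = colnames(train), drug = "toy",
    auc = c(1.0, 0.9, 0.5, 0.5, 0.1, 0.0), stringsAsFactors = FALSE))
  score <- rbind(
    UP1 = c(1, 2, 3), UP2 = c(1, 2, 3),
    DN1 = c(3, 2, 1), DN2 = c(3, 2, 1),
    HK1 = c(1, 2, 3), HK2 = c(2, 2, 2))
  colnames(score) <- c("T1", "T2", "T3")
  z_up <- c(-1, 0, 1)
  expected_z <- rbind(UP1 = z_up, UP2 = z_up, DN1 = -z_up, DN2 = -z_up, HK1 = z_up)
  colnames(expected_z) <- colnames(score)
  list(expr_train = expression_matrix(train, is_log_scale = FALSE),
       response = response,
       expr_score = expression_matrix(score, is_log_scale = FALSE),
       n_top = 2L, pseudocount = 0,
       expected = list(
         log2fc = c(UP1 = 2, UP2 = 1, DN1 = -2, DN2 = -1),
         zscore = expected_z,
         drs = c(T1 = -1.5, T2 = 0, T3 = 1.5)))
}
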