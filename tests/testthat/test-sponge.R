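# ceRNA sponge-module inference: candidate arms, join, final filter

# small world with controlled correlations for the candidate screens
sponge_world <- function(seed = 43, n = 30) {
  set.seed(seed)
  lnc_ids <- sprintf("L%02d", 1:10)
  mir_ids <- sprintf("R%02d", 1:10)
  mrna_ids <- sprintf("G%02d", 1:10)
  samples <- sprintf("T%03d", 1:n)
  groups <- stats::setNames(rep("tumor", n), samples)
  base <- matrix(rnorm(10 * n, 8), 10, n, dimnames = list(lnc_ids, samples))
  # R01..R05 anti-correlated with L01..L05; rest independent
  mirv <- matrix(rnorm(10 * n, 6), 10, n, dimnames = list(mir_ids, samples))
  for (k in 1:5) mirv[k, ] <- 6 - 0.8 * (base[k, ] - 8) + rnorm(n, 0, 0.6)
  # G01..G05 anti-correlated with R01..R05
  mrnav <- matrix(rnorm(10 * n, 7), 10, n, dimnames = list(mrna_ids, samples))
  for (k in 1:5) mrnav[k, ] <- 7 - 0.8 * (mirv[k, ] - 6) + rnorm(n, 0, 0.6)
  list(lnc = expression_matrix(base, groups),
       mir = expression_matrix(mirv, groups),
       mrna = expression_matrix(mrnav, groups),
       lnc_ids = lnc_ids, mir_ids = mir_ids, mrna_ids = mrna_ids)
}

test_that("candidate arms keep negatively correlated pairs, matching a row oracle", {
  w <- sponge_world()
  cfg <- pipeline_config()
  lnc_de <- stub_de(w$lnc_ids, rep("up", 10))
  predicted <- interaction_table(rep(w$lnc_ids, each = 10),
                                 rep(w$mir_ids, 10), evidence = "predicted")
  lm <- candidate_lnc_mir(lnc_de, predicted, w$lnc, w$mir, cfg)
  # oracle: re-screen every predicted row independently
  oracle <- apply(as.data.frame(predicted), 1, function(row) {
    sc <- spearman(w$lnc$values[row[1], ], w$mir$values[row[2], ])
    !is.na(sc$rho) && sc$rho < 0 && sc$p_value < cfg$corr_p_threshold
  })
  expect_setequal(paste(lm$source_id, lm$target_id),
                  paste(predicted$source_id, predicted$target_id)[oracle])
  expect_true(all(lm$rho < 0))
  expect_true(all(lm$p_value < cfg$corr_p_threshold))
  # the planted anti-correlated arms are present
  expect_true(all(paste0("L0", 1:5, " R0", 1:5) %in%
                    paste(lm$source_id, lm$target_id)))

  # non-DE lncRNAs never enter
  lm2 <- candidate_lnc_mir(stub_de(w$lnc_ids,
                                   c(rep("up", 5), rep("unchanged", 5))),
                           predicted, w$lnc, w$mir, cfg)
  expect_true(all(lm2$source_id %in% w$lnc_ids[1:5]))
})

test_that("pairs without expression are dropped and counted", {
  w <- sponge_world()
  predicted <- interaction_table(c("L01", "GHOST"), c("R01", "R02"),
                                 evidence = "predicted")
  lm <- candidate_lnc_mir(stub_de(c("L01", "GHOST"), c("up", "up")),
                          predicted, w$lnc, w$mir, pipeline_config())
  expect_equal(attr(lm, "n_dropped_no_expression"), 1L)
})

test_that("merge joins on the shared miRNA with product cardinality", {
  lm <- data.frame(source_id = c("L1", "L2"), target_id = "R1",
                   rho = -0.5, p_value = 0.01, stringsAsFactors = FALSE)
  mm <- data.frame(source_id = "R1", target_id = c("G1", "G2", "G3"),
                   rho = -0.6, p_value = 0.01, stringsAsFactors = FALSE)
  tri <- merge_modules(lm, mm)
  expect_equal(nrow(tri), 6L)   # 2 lncRNAs x 3 mRNAs through one miRNA
  expect_setequal(paste(tri$lncrna_id, tri$mrna_id),
                  as.vector(outer(c("L1", "L2"), c("G1", "G2", "G3"), paste)))

  mm2 <- within(mm, source_id <- "R9")
  expect_equal(nrow(merge_modules(lm, mm2)), 0L)

  # nested-loop oracle on a random fixture
  set.seed(47)
  lmr <- data.frame(source_id = sample(sprintf("L%d", 1:5), 20, TRUE),
                    target_id = sample(sprintf("R%d", 1:4), 20, TRUE),
                    rho = -runif(20), p_value = 0.01, stringsAsFactors = FALSE)
  lmr <- lmr[!duplicated(lmr[1:2]), ]
  mmr <- data.frame(source_id = sample(sprintf("R%d", 1:4), 20, TRUE),
                    target_id = sample(sprintf("G%d", 1:6), 20, TRUE),
                    rho = -runif(20), p_value = 0.01, stringsAsFactors = FALSE)
  mmr <- mmr[!duplicated(mmr[1:2]), ]
  tri2 <- merge_modules(lmr, mmr)
  oracle <- 0L
  for (i in seq_len(nrow(lmr))) for (j in seq_len(nrow(mmr)))
    if (lmr$target_id[i] == mmr$source_id[j]) oracle <- oracle + 1L
  expect_equal(nrow(tri2), oracle)
})

test_that("final filter enforces direction, positive coupling, and abundance", {
  w <- sponge_world()
  cfg <- pipeline_config()
  lnc_de <- stub_de(w$lnc_ids, rep("up", 10))
  mir_de <- stub_de(w$mir_ids, c(rep("up", 4), "down", rep("up", 5)))
  mrna_de <- stub_de(w$mrna_ids, rep("up", 10))
  predicted <- interaction_table(w$lnc_ids[1:5], w$mir_ids[1:5], "predicted")
  validated <- interaction_table(w$mir_ids[1:5], w$mrna_ids[1:5],
                                 evidence = "validated")
  lm <- candidate_lnc_mir(lnc_de, predicted, w$lnc, w$mir, cfg)
  mm <- candidate_mir_mrna(unique(lm$target_id), validated, w$mir, w$mrna, cfg)
  tri <- merge_modules(lm, mm)
  mods <- filter_modules(tri, lnc_de, mir_de, mrna_de, w$lnc, w$mrna, cfg)
  # R05 is downregulated: its triplet must be rejected whatever its correlations
  expect_false("R05" %in% mods$mirna_id)
  # every emitted module satisfies the sign and abundance invariants
  if (nrow(mods)) {
    expect_true(all(mods$rho_lnc_mir < 0))
    expect_true(all(mods$rho_mir_mrna < 0))
    expect_true(all(mods$rho_lnc_mrna > 0))
    expect_true(all(mods$mean_abundance_lnc > mods$mean_abundance_mrna))
    expect_true(all(mods$abundance_p < cfg$abundance_test_p))
  }
  # lncRNA baseline 8 vs mRNA 7: uniform dominance satisfies abundance
  expect_gte(nrow(mods), 1L)
})

test_that("tightening thresholds never increases the module count", {
  ds <- simulate_gbm_dataset(n_mrna = 40, n_lnc = 40, n_cis_pairs = 2,
                             n_host = 2, n_sponge = 6, n_decoy = 10,
                             n_tumor = 40, n_control = 10, seed = 53,
                             with_flags = FALSE)
  de_cfg <- pipeline_config(de_fc_threshold = 1.5, de_use_fdr = TRUE)
  lnc_de <- differential_expression(ds$lnc_expr, de_cfg)
  mir_de <- differential_expression(ds$mir_expr, pipeline_config())
  mrna_de <- differential_expression(ds$mrna_expr, pipeline_config())
  run <- function(cfg) {
    lm <- candidate_lnc_mir(lnc_de, ds$predicted, ds$lnc_expr, ds$mir_expr, cfg)
    mm <- candidate_mir_mrna(unique(lm$target_id), ds$validated,
                             ds$mir_expr, ds$mrna_expr, cfg)
    nrow(filter_modules(merge_modules(lm, mm), lnc_de, mir_de, mrna_de,
                        ds$lnc_expr, ds$mrna_expr, cfg))
  }
  loose <- run(pipeline_config())
  tight_p <- run(pipeline_config(corr_p_threshold = 0.005))
  tight_ab <- run(pipeline_config(abundance_test_p = 0.001))
  expect_lte(tight_p, loose)
  expect_lte(tight_ab, loose)
  expect_gte(loose, 1L)
})

test_that("the unique mRNA set deduplicates across modules", {
  mods <- data.frame(lncrna_id = c("L1", "L2", "L3"),
                     mirna_id = c("R1", "R1", "R2"),
                     mrna_id = c("G1", "G1", "G1"), stringsAsFactors = FALSE)
  expect_equal(module_gene_set(mods), "G1")
  expect_length(module_gene_set(mods[0, ]), 0L)
})
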