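# End-to-end orchestration: normalization -> differential expression ->
# positional classification -> cis/trans co-expression -> miRNA hosts ->
# sponge modules -> survival signature, with a machine-readable run summary.

#' Read a dataset directory written by [write_dataset()]
#'
#' @param dir Directory containing the files emitted by [write_dataset()].
#' @return A dataset list in the layout of [simulate_gbm_dataset()] (without
#'   `truth` unless `truth.json` is present).
#' @export
read_dataset <- function(dir) {
  p <- function(f) file.path(dir, f)
  ann <- read_annotation(p("annotation.gtf"), format = "GTF")
  out <- list(
    annotation = ann,
    lnc_expr = read_expression(p("lnc_expr.tsv"), p("samples.tsv")),
    mrna_expr = read_expression(p("mrna_expr.tsv"), p("samples.tsv")),
    mir_expr = read_expression(p("mir_expr.tsv"), p("samples.tsv")),
    predicted = read_interactions(p("predicted.tsv"), "predicted"),
    validated = read_interactions(p("validated.tsv"), "validated"),
    surv = read_survival(p("survival.tsv")))
  if (file.exists(p("truth.json")))
    out$truth <- jsonlite::read_json(p("truth.json"), simplifyVector = TRUE)
  out
}

# stage-specific threshold blocks: the study mixes cutoffs per stage
.stage_cfg <- function(cfg, ...) {
  mod <- list(...)
  for (nm in names(mod)) cfg[[nm]] <- mod[[nm]]
  cfg
}

#' Run the full lncRNA regulatory-landscape pipeline
#'
#' Executes every stage in order on an in-memory dataset (from
#' [simulate_gbm_dataset()] or [read_dataset()]): detection-flag filtering
#' and quantile normalization; differential expression per feature class
#' (lncRNA list at |FC| >= 1.5 & p < 0.05; co-expression input lists at
#' |FC| >= 2 & p < 0.05; sponge lncRNA input at FC >= 1.5 & FDR < 0.05);
#' positional subtype classification with exon-overlap removal; lncRNA-mRNA
#' and lncRNA-lncRNA cis/trans networks; miRNA host mapping with concordance
#' filtering; sponge-module inference; and the survival signature (Cox
#' screen, top-k risk score, median-split stratification, multivariate
#' adjustment). Each stage's outputs are written (when `out_dir` is given)
#' before the next begins.
#'
#' @param dataset Dataset list with elements `annotation`, `lnc_expr`,
#'   `mrna_expr`, `mir_expr`, `predicted`, `validated`, `surv`.
#' @param cfg A [pipeline_config()].
#' @param out_dir Optional output directory for stage TSVs and
#'   `run_summary.json`.
#' @param k_signature Number of lncRNAs in the survival signature.
#' @param min_present Flag-filter threshold (samples Present/Marginal).
#' @return List with the per-stage results (`de`, `subtypes`,
#'   `lnc_mrna_pairs`, `lnc_lnc_pairs`, `host_pairs`, `sponge_modules`,
#'   `signature`, `risk`, `stratification`, `multivariate`) and `summary`
#'   (stage counts, thresholds, seed, version, timestamps).
#' @export
run_pipeline <- function(dataset, cfg = pipeline_config(), out_dir = NULL,
                         k_signature = 5L, min_present = 7L) {
  need <- c("annotation", "lnc_expr", "mrna_expr", "mir_expr",
            "predicted", "validated", "surv")
  miss <- setdiff(need, names(dataset))
  if (length(miss)) stop("dataset lacks element(s): ",
                         paste(miss, collapse = ", "))
  if (!is.null(out_dir))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  emit <- function(f, writer, obj) {
    if (!is.null(out_dir)) writer(obj, file.path(out_dir, f))
  }
  summary <- list(tool = "lncscape",
                  version = as.character(utils::packageVersion("lncscape")),
                  seed = cfg$rng_seed,
                  thresholds = unclass(cfg),
                  started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                  stages = list())
  stage <- function(name, n_in, n_out, ...) {
    summary$stages[[name]] <<- c(list(n_in = n_in, n_out = n_out), list(...))
  }
  res <- list()

  # 1. flag filter + quantile normalization
  lnc_m <- dataset$lnc_expr; mrna_m <- dataset$mrna_expr
  if (!is.null(lnc_m$flags)) lnc_m <- flag_filter(lnc_m, min_present)
  if (!is.null(mrna_m$flags)) mrna_m <- flag_filter(mrna_m, min_present)
  stage("flag_filter",
        nrow(dataset$lnc_expr$values) + nrow(dataset$mrna_expr$values),
        nrow(lnc_m$values) + nrow(mrna_m$values),
        min_present = min_present)
  lnc_m <- quantile_normalize(lnc_m)
  mrna_m <- quantile_normalize(mrna_m)
  mir_m <- quantile_normalize(dataset$mir_expr)
  stage("quantile_normalize", nrow(lnc_m$values) + nrow(mrna_m$values) +
          nrow(mir_m$values),
        nrow(lnc_m$values) + nrow(mrna_m$values) + nrow(mir_m$values))

  # 2. differential expression (stage-specific thresholds)
  cfg_main <- .stage_cfg(cfg, de_fc_threshold = 1.5, de_use_fdr = FALSE)
  cfg_coex <- .stage_cfg(cfg, de_fc_threshold = 2.0, de_use_fdr = FALSE)
  cfg_sponge <- .stage_cfg(cfg, de_fc_threshold = 1.5, de_use_fdr = TRUE)
  de_lnc <- differential_expression(lnc_m, cfg_main)
  de_mrna <- differential_expression(mrna_m, cfg_coex)
  de_mir <- differential_expression(mir_m, cfg_main)
  de_lnc_coex <- differential_expression(lnc_m, cfg_coex)
  de_lnc_sponge <- differential_expression(lnc_m, cfg_sponge)
  res$de <- list(lnc = de_lnc, mrna = de_mrna, mir = de_mir)
  stage("differential_expression", nrow(lnc_m$values),
        length(de_features(de_lnc)),
        n_lnc_up = sum(de_lnc$direction == "up"),
        n_lnc_down = sum(de_lnc$direction == "down"),
        n_mrna_de = length(de_features(de_mrna)),
        n_mir_de = length(de_features(de_mir)))

  # 3. positional classification + exon-overlap removal
  ann <- dataset$annotation
  lnc_ann <- ann[ann$biotype == "lncRNA", ]
  mrna_ann <- ann[ann$biotype == "mRNA", ]
  mir_ann <- ann[ann$biotype == "miRNA", ]
  de_lnc_ids <- de_features(de_lnc)
  de_lnc_ann <- lnc_ann[lnc_ann$gene_id %in% de_lnc_ids, ]
  # classify every lncRNA once (the survival screen is annotation-based);
  # the dysregulated subset feeds the subtype summary and removal rule
  calls_all <- classify_lncrnas(lnc_ann, mrna_ann, cfg)
  res$subtypes_all <- calls_all
  calls <- calls_all[calls_all$lncrna_id %in% de_lnc_ids, , drop = FALSE]
  rownames(calls) <- NULL
  removal <- apply_exon_overlap_removal(calls, de_lnc_ann, mrna_ann)
  res$subtypes <- removal$calls
  res$subtype_summary <- subtype_summary(removal$calls)
  emit("subtypes.tsv",
       function(x, p) utils::write.table(x, p, sep = "\t", quote = FALSE,
                                         row.names = FALSE),
       removal$calls)
  stage("subtype_classification", nrow(calls), length(removal$kept),
        n_removed_exon_rule = length(removal$removed))
  kept_lnc <- removal$kept

  # 4. co-expression networks (DE lists at the coexpression thresholds,
  # restricted to lncRNAs surviving the exon rule)
  de_lnc_net <- de_lnc_coex[de_lnc_coex$feature_id %in% kept_lnc, ]
  pairs_lm <- build_network(de_lnc_net, de_mrna, lnc_m, mrna_m, ann, cfg)
  pairs_ll <- build_network(de_lnc_net, NULL, lnc_m, NULL, ann, cfg)
  res$lnc_mrna_pairs <- pairs_lm
  res$lnc_lnc_pairs <- pairs_ll
  emit("lnc_mrna_pairs.tsv", write_pairs, pairs_lm)
  emit("lnc_lnc_pairs.tsv", write_pairs, pairs_ll)
  c_lm <- attr(pairs_lm, "counts"); c_ll <- attr(pairs_ll, "counts")
  stage("coexpression_lnc_mrna", c_lm$n_enumerated, nrow(pairs_lm),
        n_cis = c_lm$n_cis, n_trans = c_lm$n_trans,
        n_cis_kept = c_lm$n_cis_kept, n_trans_kept = c_lm$n_trans_kept)
  stage("coexpression_lnc_lnc", c_ll$n_enumerated, nrow(pairs_ll),
        n_self_removed = c_ll$n_self_removed,
        n_after_dedup = c_ll$n_after_dedup,
        n_cis_kept = c_ll$n_cis_kept, n_trans_kept = c_ll$n_trans_kept)

  # 5. miRNA hosts
  hosts_raw <- intersect_hosts(de_lnc_ann, mir_ann)
  hosts <- filter_concordant(hosts_raw, de_lnc, de_mir, lnc_m, mir_m)
  res$host_pairs <- hosts
  emit("hosts.tsv",
       function(x, p) utils::write.table(x, p, sep = "\t", quote = FALSE,
                                         row.names = FALSE), hosts)
  stage("mirna_hosts", nrow(hosts_raw), nrow(hosts))

  # 6. sponge modules
  lm <- candidate_lnc_mir(de_lnc_sponge, dataset$predicted, lnc_m, mir_m, cfg)
  mm <- candidate_mir_mrna(unique(lm$target_id), dataset$validated,
                           mir_m, mrna_m, cfg)
  raw_triplets <- merge_modules(lm, mm)
  modules <- filter_modules(raw_triplets, de_lnc_sponge, de_mir, de_mrna,
                            lnc_m, mrna_m, cfg)
  res$sponge_modules <- modules
  emit("sponge_modules.tsv", write_modules, modules)
  stage("sponge_modules", nrow(raw_triplets), nrow(modules),
        n_lnc_mir = nrow(lm), n_mir_mrna = nrow(mm),
        n_unique_mrna = length(module_gene_set(modules)))

  # 7. survival signature
  eligible <- eligibility_filter(lnc_m, calls_all, cfg)
  surv <- dataset$surv
  screen <- cox_screen(lnc_m, surv, features = eligible)
  sel <- select_signature(screen, k = k_signature)
  scores <- risk_score(sel, lnc_m, samples = surv$sample_id)
  strat <- stratify_and_test(scores, surv)
  multi <- if (length(surv_covariate_names(surv)))
    multivariate_cox(scores, surv) else NULL
  res$cox_screen <- screen
  res$signature <- sel
  res$risk <- scores
  res$stratification <- strat
  res$multivariate <- multi
  emit("cox_screen.tsv",
       function(x, p) utils::write.table(x, p, sep = "\t", quote = FALSE,
                                         row.names = FALSE), screen)
  emit("risk_scores.tsv",
       function(x, p) utils::write.table(x, p, sep = "\t", quote = FALSE,
                                         row.names = FALSE), scores)
  emit("km_curves.tsv",
       function(x, p) utils::write.table(x, p, sep = "\t", quote = FALSE,
                                         row.names = FALSE), strat$km)
  stage("survival_signature", length(eligible), nrow(sel),
        logrank_p = strat$logrank_p,
        median_survival_low = unname(strat$median_survival["low"]),
        median_survival_high = unname(strat$median_survival["high"]))

  summary$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  res$summary <- summary
  if (!is.null(out_dir))
    jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  res
}

#' Strip volatile fields from a run summary
#'
#' Removes wall-clock timestamps so that two runs with identical seed and
#' configuration compare equal.
#'
#' @param summary The `summary` element of a [run_pipeline()] result.
#' @return The summary without `started`/`finished`.
#' @export
summary_fingerprint <- function(summary) {
  summary$started <- NULL
  summary$finished <- NULL
  summary
}
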