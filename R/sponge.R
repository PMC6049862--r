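# ceRNA (sponge) module inference: the six-filter chain that assembles
# lncRNA -| miRNA -| mRNA triplets in which an abundant, upregulated lncRNA
# plausibly titrates a shared miRNA away from its mRNA target.
#
# Filter chain: (1) DE lncRNAs at the stage fold-change/FDR cutoffs;
# (2) predicted lncRNA-miRNA pairs with negative correlation; (3) validated
# miRNA-mRNA pairs with negative correlation; (4) inner join on the miRNA;
# (5) all three members upregulated and lncRNA-mRNA positively correlated;
# (6) lncRNA abundance significantly above mRNA abundance in tumors.

# shared tumor samples of two expression matrices
.shared_tumor_samples <- function(a, b, stage) {
  samp <- intersect(colnames(a$values), colnames(b$values))
  samp <- samp[a$groups[samp] == "tumor"]
  if (length(samp) < 4L)
    stop("fewer than 4 shared tumor samples at stage: ", stage)
  samp
}

# negative-correlation screen of an interaction table against two matrices
.corr_screen <- function(tab, src_expr, tgt_expr, cfg, stage,
                         require_p = TRUE) {
  samp <- .shared_tumor_samples(src_expr, tgt_expr, stage)
  n_missing <- 0L
  out <- vector("list", nrow(tab))
  for (k in seq_len(nrow(tab))) {
    s <- tab$source_id[k]; t <- tab$target_id[k]
    if (!(s %in% rownames(src_expr$values)) ||
        !(t %in% rownames(tgt_expr$values))) {
      n_missing <- n_missing + 1L
      next
    }
    sc <- spearman(src_expr$values[s, samp], tgt_expr$values[t, samp])
    if (is.na(sc$rho)) { n_missing <- n_missing + 1L; next }
    ok <- sc$rho < 0 && (!require_p || sc$p_value < cfg$corr_p_threshold)
    if (ok)
      out[[k]] <- data.frame(source_id = s, target_id = t,
                             rho = sc$rho, p_value = sc$p_value,
                             stringsAsFactors = FALSE)
  }
  res <- if (any(!vapply(out, is.null, TRUE)))
    do.call(rbind, out[!vapply(out, is.null, TRUE)]) else
    data.frame(source_id = character(0), target_id = character(0),
               rho = numeric(0), p_value = numeric(0),
               stringsAsFactors = FALSE)
  attr(res, "n_dropped_no_expression") <- n_missing
  rownames(res) <- NULL
  res
}

#' Candidate lncRNA-miRNA sponge arms
#'
#' Restricts a predicted-interaction table (miRcode-like) to differentially
#' expressed lncRNAs and keeps pairs whose tumor-sample Spearman correlation
#' is negative with `p < cfg$corr_p_threshold` (set `require_p = FALSE` for a
#' pure sign screen).
#'
#' @param lnc_de [differential_expression()] table for lncRNAs (stage
#'   convention: fold change >= 1.5, FDR < 0.05).
#' @param predicted An [interaction_table()] of predicted lncRNA->miRNA pairs.
#' @param lnc_expr,mir_expr [expression_matrix()] objects.
#' @param cfg A [pipeline_config()].
#' @param require_p Logical; also require `p < cfg$corr_p_threshold`.
#' @return Data frame `source_id` (lncRNA), `target_id` (miRNA), `rho`,
#'   `p_value`, with attribute `n_dropped_no_expression`.
#' @export
candidate_lnc_mir <- function(lnc_de, predicted, lnc_expr, mir_expr,
                              cfg = pipeline_config(), require_p = TRUE) {
  stopifnot(attr(predicted, "evidence") == "predicted")
  de_ids <- de_features(lnc_de)
  tab <- predicted[predicted$source_id %in% de_ids, , drop = FALSE]
  .corr_screen(tab, lnc_expr, mir_expr, cfg, "candidate_lnc_mir", require_p)
}

#' Candidate miRNA-mRNA sponge arms
#'
#' Restricts a validated-interaction table (miRWalk-like) to the given miRNAs
#' and keeps negatively correlated pairs, as in [candidate_lnc_mir()].
#'
#' @param mirs Character vector of miRNA ids emerging from the lncRNA arm.
#' @param validated An [interaction_table()] of validated miRNA->mRNA pairs.
#' @param mir_expr,mrna_expr [expression_matrix()] objects.
#' @param cfg A [pipeline_config()].
#' @param require_p Logical; also require `p < cfg$corr_p_threshold`.
#' @return Data frame `source_id` (miRNA), `target_id` (mRNA), `rho`,
#'   `p_value`, with attribute `n_dropped_no_expression`.
#' @export
candidate_mir_mrna <- function(mirs, validated, mir_expr, mrna_expr,
                               cfg = pipeline_config(), require_p = TRUE) {
  stopifnot(attr(validated, "evidence") == "validated")
  tab <- validated[validated$source_id %in% mirs, , drop = FALSE]
  .corr_screen(tab, mir_expr, mrna_expr, cfg, "candidate_mir_mrna", require_p)
}

#' Merge the two sponge arms into raw triplets
#'
#' Inner join on the shared miRNA: one triplet per (lncRNA, miRNA) x
#' (miRNA, mRNA) combination.
#'
#' @param lm Output of [candidate_lnc_mir()].
#' @param mm Output of [candidate_mir_mrna()].
#' @return Data frame `lncrna_id`, `mirna_id`, `mrna_id`, `rho_lnc_mir`,
#'   `p_lnc_mir`, `rho_mir_mrna`, `p_mir_mrna`.
#' @export
merge_modules <- function(lm, mm) {
  merged <- merge(
    data.frame(lncrna_id = lm$source_id, mirna_id = lm$target_id,
               rho_lnc_mir = lm$rho, p_lnc_mir = lm$p_value,
               stringsAsFactors = FALSE),
    data.frame(mirna_id = mm$source_id, mrna_id = mm$target_id,
               rho_mir_mrna = mm$rho, p_mir_mrna = mm$p_value,
               stringsAsFactors = FALSE),
    by = "mirna_id")
  merged[, c("lncrna_id", "mirna_id", "mrna_id",
             "rho_lnc_mir", "p_lnc_mir", "rho_mir_mrna", "p_mir_mrna")]
}

#' Final sponge-module filter
#'
#' Keeps raw triplets in which (i) lncRNA, miRNA and mRNA are all
#' upregulated; (ii) the lncRNA-mRNA tumor correlation is positive with
#' `p < cfg$corr_p_threshold`; and (iii) a one-sided paired test across tumor
#' samples shows lncRNA log2 abundance above mRNA log2 abundance at
#' `p < cfg$abundance_test_p` (Wilcoxon signed-rank by default, paired t with
#' `cfg$abundance_test = "t"`). All three conditions are mandatory; every
#' emitted module satisfies the sign invariants (negative lncRNA-miRNA and
#' miRNA-mRNA arms, positive lncRNA-mRNA, higher mean lncRNA abundance).
#'
#' @param triplets Output of [merge_modules()].
#' @param lnc_de,mir_de,mrna_de [differential_expression()] tables.
#' @param lnc_expr,mrna_expr [expression_matrix()] objects (log2).
#' @param cfg A [pipeline_config()].
#' @return Data frame of modules: the triplet ids, the three correlations and
#'   p-values, `abundance_stat`, `abundance_p`, `mean_abundance_lnc`,
#'   `mean_abundance_mrna`; attribute `attrition` logs counts after each
#'   filter.
#' @export
filter_modules <- function(triplets, lnc_de, mir_de, mrna_de,
                           lnc_expr, mrna_expr, cfg = pipeline_config()) {
  samp <- .shared_tumor_samples(lnc_expr, mrna_expr, "filter_modules")
  attrition <- list(n_raw = nrow(triplets))

  up <- function(de, ids) de$direction[match(ids, de$feature_id)] == "up"
  all_up <- up(lnc_de, triplets$lncrna_id) & up(mir_de, triplets$mirna_id) &
    up(mrna_de, triplets$mrna_id)
  all_up[is.na(all_up)] <- FALSE
  tri <- triplets[all_up, , drop = FALSE]
  attrition$n_all_up <- nrow(tri)

  keep <- logical(nrow(tri))
  rho_lm <- p_lm <- ab_stat <- ab_p <- mu_l <- mu_m <- rep(NA_real_, nrow(tri))
  for (k in seq_len(nrow(tri))) {
    l <- tri$lncrna_id[k]; m <- tri$mrna_id[k]
    if (!(l %in% rownames(lnc_expr$values)) ||
        !(m %in% rownames(mrna_expr$values))) next
    xl <- lnc_expr$values[l, samp]; xm <- mrna_expr$values[m, samp]
    sc <- spearman(xl, xm)
    rho_lm[k] <- sc$rho; p_lm[k] <- sc$p_value
    if (is.na(sc$rho) || sc$rho <= 0 || sc$p_value >= cfg$corr_p_threshold)
      next
    d <- xl - xm
    ab <- if (cfg$abundance_test == "wilcoxon")
      suppressWarnings(stats::wilcox.test(d, alternative = "greater",
                                          exact = FALSE))
    else stats::t.test(d, alternative = "greater")
    ab_stat[k] <- unname(ab$statistic); ab_p[k] <- ab$p.value
    mu_l[k] <- mean(xl); mu_m[k] <- mean(xm)
    keep[k] <- ab$p.value < cfg$abundance_test_p && mean(xl) > mean(xm)
  }
  pos_corr <- !is.na(rho_lm) & rho_lm > 0 & p_lm < cfg$corr_p_threshold
  attrition$n_pos_corr <- sum(pos_corr)
  out <- cbind(tri, rho_lnc_mrna = rho_lm, p_lnc_mrna = p_lm,
               abundance_stat = ab_stat, abundance_p = ab_p,
               mean_abundance_lnc = mu_l, mean_abundance_mrna = mu_m)[keep, ,
                                                                     drop = FALSE]
  attrition$n_final <- nrow(out)
  # hard assertion of the module invariants on every run
  stopifnot(all(out$rho_lnc_mir < 0), all(out$rho_mir_mrna < 0),
            all(out$rho_lnc_mrna > 0),
            all(out$mean_abundance_lnc > out$mean_abundance_mrna),
            all(out$abundance_p < cfg$abundance_test_p))
  rownames(out) <- NULL
  attr(out, "attrition") <- attrition
  out
}

#' Unique mRNA set of a module list
#'
#' The deduplicated mRNA ids of the final sponge modules (the gene set a user
#' would hand to an external enrichment tool).
#'
#' @param modules Output of [filter_modules()].
#' @return Character vector of unique mRNA ids.
#' @export
module_gene_set <- function(modules) {
  unique(modules$mrna_id)
}
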