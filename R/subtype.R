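# Positional classification of lncRNAs relative to protein-coding genes:
# six mutually exclusive subtypes plus the exon-sense-overlap removal rule
# that guards against probes measuring mRNA signal.

SUBTYPE_LEVELS <- c("exon_sense_overlapping", "natural_antisense",
                    "intron_sense_overlapping", "intronic_antisense",
                    "bidirectional", "intergenic")

# half-open interval overlap
.spans_overlap <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1

# TSS coordinate: start on '+', end on '-'
.tss <- function(start, end, strand) ifelse(strand == "+", start, end)

#' Classify lncRNAs into positional subtypes
#'
#' Assigns each lncRNA exactly one of six subtypes from its geometry relative
#' to protein-coding (mRNA) genes, with the precedence
#' exon_sense_overlapping > natural_antisense > intron_sense_overlapping >
#' intronic_antisense > bidirectional > intergenic:
#'
#' * `exon_sense_overlapping` — span overlaps an mRNA exon on the same strand;
#' * `natural_antisense` — span overlaps an mRNA exon on the opposite strand;
#' * `intron_sense_overlapping` — span lies wholly inside one intron of a
#'   same-strand mRNA;
#' * `intronic_antisense` — as above but on the opposite strand;
#' * `bidirectional` — opposite strands, no span overlap, TSS-to-TSS distance
#'   at most `cfg$bidirectional_tss_window` (inclusive; TSS is the gene start
#'   on `+` and the gene end on `-`);
#' * `intergenic` — none of the above.
#'
#' @param lncs,mrnas [gene_annotation()] tables of lncRNAs and mRNAs.
#' @param cfg A [pipeline_config()].
#' @return Data frame with columns `lncrna_id`, `subtype`, `partner_gene_id`
#'   (`NA` for intergenic), `removed_by_exon_rule` (all `FALSE`; see
#'   [apply_exon_overlap_removal()]).
#' @export
classify_lncrnas <- function(lncs, mrnas, cfg = pipeline_config()) {
  stopifnot(inherits(lncs, "gene_annotation"), inherits(mrnas, "gene_annotation"))
  chrom_missing <- setdiff(unique(lncs$chrom), unique(mrnas$chrom))
  if (length(chrom_missing))
    warning("lncRNA chromosome(s) absent from mRNA annotation: ",
            paste(chrom_missing, collapse = ", "),
            " - those lncRNAs are called intergenic")
  out <- lapply(seq_len(nrow(lncs)), function(i)
    classify_one_lncrna(lncs[i, ], mrnas, cfg))
  calls <- do.call(rbind, out)
  calls$removed_by_exon_rule <- FALSE
  rownames(calls) <- NULL
  calls
}

classify_one_lncrna <- function(lnc, mrnas, cfg) {
  cand <- mrnas[mrnas$chrom == lnc$chrom, , drop = FALSE]
  best_rank <- length(SUBTYPE_LEVELS)   # intergenic
  best_partner <- NA_character_
  best_dist <- Inf
  for (j in seq_len(nrow(cand))) {
    g <- cand[j, ]
    same <- g$strand == lnc$strand
    ex <- g$exons[[1L]]
    sub <- NULL
    if (any(.spans_overlap(lnc$start, lnc$end, ex[, 1L], ex[, 2L]))) {
      sub <- if (same) "exon_sense_overlapping" else "natural_antisense"
    } else if (nrow(ex) > 1L &&
               any(lnc$start >= ex[-nrow(ex), 2L] & lnc$end <= ex[-1L, 1L])) {
      sub <- if (same) "intron_sense_overlapping" else "intronic_antisense"
    } else if (!same && !.spans_overlap(lnc$start, lnc$end, g$start, g$end)) {
      d <- abs(.tss(lnc$start, lnc$end, lnc$strand) -
               .tss(g$start, g$end, g$strand))
      if (d <= cfg$bidirectional_tss_window) sub <- "bidirectional"
    }
    if (is.null(sub)) next
    r <- match(sub, SUBTYPE_LEVELS)
    d <- .gene_gap(lnc, g)
    if (r < best_rank || (r == best_rank && d < best_dist)) {
      best_rank <- r; best_partner <- g$gene_id; best_dist <- d
    }
  }
  data.frame(lncrna_id = lnc$gene_id,
             subtype = SUBTYPE_LEVELS[best_rank],
             partner_gene_id = best_partner,
             stringsAsFactors = FALSE)
}

# bp gap between two gene spans (0 when overlapping); ties between equally
# ranked partners break towards the nearer gene
.gene_gap <- function(a, b) {
  max(0L, max(a$start, b$start) - min(a$end, b$end))
}

#' Remove lncRNAs wholly contained in same-strand mRNA exons
#'
#' Drops lncRNAs whose entire span lies within the union of same-strand,
#' same-chromosome mRNA exon intervals — the geometry in which a microarray
#' probe cannot distinguish lncRNA signal from the overlapping mRNA. Partial
#' exon overlaps are retained.
#'
#' @param calls Output of [classify_lncrnas()].
#' @param lncs,mrnas The [gene_annotation()] tables used for classification.
#' @return List with `calls` (the input with `removed_by_exon_rule` updated),
#'   `kept` and `removed` (character id vectors).
#' @export
apply_exon_overlap_removal <- function(calls, lncs, mrnas) {
  stopifnot(all(calls$lncrna_id %in% lncs$gene_id))
  removed <- logical(nrow(calls))
  cand_idx <- which(calls$subtype == "exon_sense_overlapping")
  for (i in cand_idx) {
    lnc <- lncs[match(calls$lncrna_id[i], lncs$gene_id), ]
    same <- mrnas[mrnas$chrom == lnc$chrom & mrnas$strand == lnc$strand, ,
                  drop = FALSE]
    if (!nrow(same)) next
    ex <- do.call(rbind, same$exons)
    ex <- ex[order(ex[, 1L]), , drop = FALSE]
    # union of exon footprint, merging overlapping or abutting intervals
    merged <- ex[1L, , drop = FALSE]
    for (k in seq_len(nrow(ex))[-1L]) {
      last <- nrow(merged)
      if (ex[k, 1L] <= merged[last, 2L])
        merged[last, 2L] <- max(merged[last, 2L], ex[k, 2L])
      else merged <- rbind(merged, ex[k, , drop = FALSE])
    }
    removed[i] <- any(lnc$start >= merged[, 1L] & lnc$end <= merged[, 2L])
  }
  calls$removed_by_exon_rule <- removed
  list(calls = calls,
       kept = calls$lncrna_id[!removed],
       removed = calls$lncrna_id[removed])
}

#' Subtype composition summary
#'
#' Counts and percentages per positional subtype, the numbers behind a
#' pie-chart view of a dysregulated lncRNA set.
#'
#' @param calls Output of [classify_lncrnas()].
#' @return Data frame with columns `subtype`, `count`, `percentage`
#'   (rounded to 2 decimals).
#' @export
subtype_summary <- function(calls) {
  if (!nrow(calls)) stop("no subtype calls to summarize")
  tab <- table(factor(calls$subtype, levels = SUBTYPE_LEVELS))
  data.frame(subtype = names(tab),
             count = as.integer(tab),
             percentage = round(100 * as.integer(tab) / nrow(calls), 2L),
             row.names = NULL, stringsAsFactors = FALSE)
}
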