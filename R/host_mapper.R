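# lncRNAs as miRNA host genes: genomic-interval intersection of lncRNA spans
# with miRNA hairpin coordinates, then retention of concordantly regulated
# host/miRNA pairs.

#' Intersect lncRNA spans with miRNA coordinates
#'
#' One pair per overlapping (lncRNA, miRNA) combination, with the coordinate
#' intersection as the overlap interval (>= 1 bp, the BEDtools-intersect
#' default). By default the miRNA must lie on the lncRNA's strand — a host
#' transcript carries the hairpin on its own strand; `require_same_strand =
#' FALSE` reproduces strand-blind intersection.
#'
#' @param lncs,mirnas [gene_annotation()] tables.
#' @param require_same_strand Logical.
#' @return Data frame with columns `lncrna_id`, `mirna_id`, `chrom`,
#'   `overlap_start`, `overlap_end`, `same_strand`.
#' @export
intersect_hosts <- function(lncs, mirnas, require_same_strand = TRUE) {
  stopifnot(inherits(lncs, "gene_annotation"), inherits(mirnas, "gene_annotation"))
  if (!nrow(lncs) || !nrow(mirnas))
    return(.empty_host_pairs())
  gr_l <- GenomicRanges::GRanges(lncs$chrom,
                                 IRanges::IRanges(lncs$start + 1L, lncs$end),
                                 strand = lncs$strand)
  gr_m <- GenomicRanges::GRanges(mirnas$chrom,
                                 IRanges::IRanges(mirnas$start + 1L, mirnas$end),
                                 strand = mirnas$strand)
  hits <- GenomicRanges::findOverlaps(gr_l, gr_m, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  same <- lncs$strand[qi] == mirnas$strand[si]
  if (require_same_strand) { qi <- qi[same]; si <- si[same]; same <- same[same] }
  if (!length(qi)) return(.empty_host_pairs())
  data.frame(lncrna_id = lncs$gene_id[qi],
             mirna_id = mirnas$gene_id[si],
             chrom = lncs$chrom[qi],
             overlap_start = pmax(lncs$start[qi], mirnas$start[si]),
             overlap_end = pmin(lncs$end[qi], mirnas$end[si]),
             same_strand = same,
             stringsAsFactors = FALSE)
}

.empty_host_pairs <- function() {
  data.frame(lncrna_id = character(0), mirna_id = character(0),
             chrom = character(0), overlap_start = integer(0),
             overlap_end = integer(0), same_strand = logical(0),
             stringsAsFactors = FALSE)
}

#' Retain concordantly regulated host lncRNA / miRNA pairs
#'
#' Keeps host pairs in which the lncRNA and its embedded miRNA are
#' differentially expressed in the same direction (up/up or down/down),
#' mirroring the host-gene table in which lncRNA regulation (RNA-Seq) and
#' miRNA regulation (microarray) come from different assays. When both
#' expression matrices are supplied and share samples, each retained pair is
#' annotated with the sample-wise Spearman rho and p between host and miRNA;
#' pairs lacking expression keep `NA` there and are retained on direction
#' alone.
#'
#' @param pairs Output of [intersect_hosts()].
#' @param lnc_de,mir_de [differential_expression()] tables for lncRNAs and
#'   miRNAs.
#' @param lnc_expr,mir_expr Optional [expression_matrix()] objects for the
#'   correlation annotation.
#' @param use_samples Samples used for the correlation (`"tumor"` default).
#' @return The concordant subset of `pairs` with added columns
#'   `lnc_log2_fc`, `lnc_direction`, `mir_log2_fc`, `mir_direction`, `rho`,
#'   `corr_p`.
#' @export
filter_concordant <- function(pairs, lnc_de, mir_de,
                              lnc_expr = NULL, mir_expr = NULL,
                              use_samples = "tumor") {
  li <- match(pairs$lncrna_id, lnc_de$feature_id)
  mi <- match(pairs$mirna_id, mir_de$feature_id)
  pairs$lnc_log2_fc <- lnc_de$log2_fc[li]
  pairs$lnc_direction <- lnc_de$direction[li]
  pairs$mir_log2_fc <- mir_de$log2_fc[mi]
  pairs$mir_direction <- mir_de$direction[mi]
  keep <- !is.na(pairs$lnc_direction) & !is.na(pairs$mir_direction) &
    pairs$lnc_direction %in% c("up", "down") &
    pairs$lnc_direction == pairs$mir_direction
  out <- pairs[keep, , drop = FALSE]
  out$rho <- rep(NA_real_, nrow(out))
  out$corr_p <- rep(NA_real_, nrow(out))
  if (!is.null(lnc_expr) && !is.null(mir_expr) && nrow(out)) {
    samp <- intersect(colnames(lnc_expr$values), colnames(mir_expr$values))
    if (use_samples != "all")
      samp <- samp[lnc_expr$groups[samp] == use_samples]
    if (length(samp) >= 4L) {
      for (k in seq_len(nrow(out))) {
        l <- out$lncrna_id[k]; m <- out$mirna_id[k]
        if (l %in% rownames(lnc_expr$values) && m %in% rownames(mir_expr$values)) {
          sc <- spearman(lnc_expr$values[l, samp], mir_expr$values[m, samp])
          out$rho[k] <- sc$rho; out$corr_p[k] <- sc$p_value
        }
      }
    }
  }
  rownames(out) <- NULL
  out
}
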