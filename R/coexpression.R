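# Sample-wise Spearman co-expression networks between differentially
# expressed features, split into cis pairs (inside a +/-500 kb genomic
# window) and trans pairs (outside it, or inter-chromosomal) with the
# study's stage-specific retention thresholds.

#' Spearman correlation with t-approximation p-value
#'
#' Rho is Pearson correlation of mean-ranked values (ties get average ranks);
#' the p-value comes from the t approximation on n - 2 degrees of freedom,
#' the large-sample route used for million-scale pair screens where exact
#' permutation is infeasible.
#'
#' @param x,y Equal-length numeric vectors, n >= 4, finite values.
#' @return List with `rho` and `p_value`. A constant vector yields `rho = NA`
#'   (callers skip such pairs and count them).
#' @examples
#' spearman(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))  # rho = 0.8
#' @export
spearman <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 4L, all(is.finite(x)), all(is.finite(y)))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p_value = NA_real_))
  rho <- stats::cor(rank(x), rank(y))
  list(rho = rho, p_value = .spearman_p(rho, n))
}

.spearman_p <- function(rho, n) {
  p <- numeric(length(rho))
  sat <- abs(rho) >= 1
  p[sat] <- 0
  r <- rho[!sat]
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p[!sat] <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p
}

#' Classify a gene pair as cis or trans
#'
#' Cis means same chromosome and partner span within `cfg$cis_window` bp of
#' the anchor gene's span (boundary inclusive: a gap of exactly the window
#' size is still cis); anything else, including inter-chromosomal pairs, is
#' trans.
#'
#' @param a,b Single-row [gene_annotation()] entries (a is the anchor, e.g.
#'   the lncRNA).
#' @param cfg A [pipeline_config()].
#' @return List with `distance_class` (`"cis"`/`"trans"`) and `genomic_gap`
#'   (bp between spans, 0 when overlapping, `NA` across chromosomes).
#' @export
classify_pair_distance <- function(a, b, cfg = pipeline_config()) {
  if (a$chrom != b$chrom)
    return(list(distance_class = "trans", genomic_gap = NA_integer_))
  gap <- max(0L, max(a$start, b$start) - min(a$end, b$end))
  list(distance_class = if (gap <= cfg$cis_window) "cis" else "trans",
       genomic_gap = as.integer(gap))
}

# vectorized cis test: anchor row `a` against annotation columns
.cis_vec <- function(a_chrom, a_start, a_end, b_chrom, b_start, b_end, w) {
  gap <- pmax(0L, pmax(a_start, b_start) - pmin(a_end, b_end))
  list(cis = b_chrom == a_chrom & gap <= w,
       gap = ifelse(b_chrom == a_chrom, gap, NA_integer_))
}

#' Build a cis/trans co-expression network
#'
#' Enumerates every cross pair between two differentially expressed feature
#' sets (or the self-cross of one set in `lnc_lnc` mode), computes sample-wise
#' Spearman correlation over the selected samples, classifies each pair
#' cis/trans by the genomic window, and retains cis pairs at
#' `p < cfg$corr_p_threshold` and trans pairs at that p cutoff plus
#' `|rho| > cfg$trans_abs_rho_threshold`. In `lnc_lnc` mode self-pairs are
#' removed and symmetric duplicates collapse to one record with
#' `a_id < b_id`. Correlations are computed in feature chunks so the full
#' pair cross product is never materialized as rho/p matrices.
#'
#' @param a_de,b_de [differential_expression()] tables for the two feature
#'   sets; omit `b_de` (NULL) for the lncRNA-lncRNA self-cross.
#' @param a_expr,b_expr Matching [expression_matrix()] objects (log2).
#' @param annotations A [gene_annotation()] table covering both feature sets.
#' @param cfg A [pipeline_config()].
#' @param use_samples `"tumor"` (default, as in the study), `"control"` or
#'   `"all"`.
#' @param chunk_size Number of anchor features correlated per block.
#' @return Data frame of retained pairs (columns `a_id`, `b_id`, `pair_kind`,
#'   `rho`, `p_value`, `fdr`, `distance_class`, `quadrant`, `genomic_gap`)
#'   with an attribute `counts`: `n_a`, `n_b`, `n_enumerated`,
#'   `n_self_removed`, `n_after_dedup`, `n_cis`, `n_trans`,
#'   `n_skipped_constant`, `n_cis_kept`, `n_trans_kept`. FDR is
#'   Benjamini-Hochberg across all tested pairs, reported but not used for
#'   filtering.
#' @export
build_network <- function(a_de, b_de = NULL, a_expr, b_expr = NULL,
                          annotations, cfg = pipeline_config(),
                          use_samples = c("tumor", "control", "all"),
                          chunk_size = 512L) {
  use_samples <- match.arg(use_samples)
  lnc_lnc <- is.null(b_de)
  if (lnc_lnc) { b_de <- a_de; b_expr <- a_expr }
  stopifnot(inherits(a_expr, "expression_matrix"),
            inherits(b_expr, "expression_matrix"))

  a_ids <- intersect(de_features(a_de), rownames(a_expr$values))
  b_ids <- intersect(de_features(b_de), rownames(b_expr$values))
  no_ann <- setdiff(c(a_ids, b_ids), annotations$gene_id)
  if (length(no_ann)) {
    warning(length(no_ann), " DE feature(s) lack annotation and are excluded")
    a_ids <- setdiff(a_ids, no_ann); b_ids <- setdiff(b_ids, no_ann)
  }
  if (!length(a_ids) || !length(b_ids)) stop("empty DE feature set")

  samp <- switch(use_samples,
                 tumor = names(a_expr$groups)[a_expr$groups == "tumor"],
                 control = names(a_expr$groups)[a_expr$groups == "control"],
                 all = names(a_expr$groups))
  samp <- intersect(samp, colnames(b_expr$values))
  if (length(samp) < 4L) stop("need >= 4 shared samples for correlation")

  ra <- t(apply(a_expr$values[a_ids, samp, drop = FALSE], 1L, rank))
  rb <- t(apply(b_expr$values[b_ids, samp, drop = FALSE], 1L, rank))
  const_a <- apply(ra, 1L, stats::sd) == 0
  const_b <- apply(rb, 1L, stats::sd) == 0
  n_samp <- length(samp)

  ann_a <- annotations[match(a_ids, annotations$gene_id), ]
  ann_b <- annotations[match(b_ids, annotations$gene_id), ]
  dir_a <- a_de$direction[match(a_ids, a_de$feature_id)]
  dir_b <- b_de$direction[match(b_ids, b_de$feature_id)]

  n_a <- length(a_ids); n_b <- length(b_ids)
  counts <- list(n_a = n_a, n_b = n_b,
                 n_enumerated = n_a * n_b,
                 n_self_removed = if (lnc_lnc) n_a else 0L,
                 n_after_dedup = if (lnc_lnc) (n_a * n_b - n_a) / 2 else n_a * n_b,
                 n_cis = 0L, n_trans = 0L, n_skipped_constant = 0L,
                 n_cis_kept = 0L, n_trans_kept = 0L)

  kept <- list()
  all_p <- list()          # p of every tested pair, for the FDR column
  kept_p_index <- list()   # position of each kept pair in the tested stream
  tested <- 0L

  for (off in seq(1L, n_a, by = chunk_size)) {
    ai <- off:min(off + chunk_size - 1L, n_a)
    rho_blk <- stats::cor(t(ra[ai, , drop = FALSE]), t(rb))
    for (ii in seq_along(ai)) {
      i <- ai[ii]
      jsel <- if (lnc_lnc) which(seq_len(n_b) > i) else seq_len(n_b)
      if (!length(jsel)) next
      rho <- rho_blk[ii, jsel]
      usable <- !const_a[i] & !const_b[jsel] & !is.na(rho)
      counts$n_skipped_constant <- counts$n_skipped_constant + sum(!usable)

      cis <- .cis_vec(ann_a$chrom[i], ann_a$start[i], ann_a$end[i],
                      ann_b$chrom[jsel], ann_b$start[jsel], ann_b$end[jsel],
                      cfg$cis_window)
      counts$n_cis <- counts$n_cis + sum(cis$cis)
      counts$n_trans <- counts$n_trans + sum(!cis$cis)

      p <- rep(NA_real_, length(jsel))
      p[usable] <- .spearman_p(rho[usable], n_samp)
      all_p[[length(all_p) + 1L]] <- p
      keep <- usable & p < cfg$corr_p_threshold &
        (cis$cis | abs(rho) > cfg$trans_abs_rho_threshold)
      if (any(keep)) {
        j <- jsel[keep]
        counts$n_cis_kept <- counts$n_cis_kept + sum(cis$cis[keep])
        counts$n_trans_kept <- counts$n_trans_kept + sum(!cis$cis[keep])
        kept[[length(kept) + 1L]] <- data.frame(
          a_id = a_ids[i], b_id = b_ids[j],
          pair_kind = if (lnc_lnc) "lnc_lnc" else "lnc_mrna",
          rho = rho[keep], p_value = p[keep],
          distance_class = ifelse(cis$cis[keep], "cis", "trans"),
          quadrant = paste(dir_a[i], dir_b[j], sep = "_"),
          genomic_gap = cis$gap[keep],
          stringsAsFactors = FALSE)
        kept_p_index[[length(kept_p_index) + 1L]] <- tested + which(keep)
      }
      tested <- tested + length(jsel)
    }
  }

  pairs <- if (length(kept)) do.call(rbind, kept) else
    data.frame(a_id = character(0), b_id = character(0),
               pair_kind = character(0), rho = numeric(0),
               p_value = numeric(0), distance_class = character(0),
               quadrant = character(0), genomic_gap = integer(0),
               stringsAsFactors = FALSE)
  fdr_all <- stats::p.adjust(unlist(all_p), method = "BH")
  pairs$fdr <- if (nrow(pairs)) fdr_all[unlist(kept_p_index)] else numeric(0)
  pairs <- pairs[, c("a_id", "b_id", "pair_kind", "rho", "p_value", "fdr",
                     "distance_class", "quadrant", "genomic_gap")]
  rownames(pairs) <- NULL
  attr(pairs, "counts") <- counts
  pairs
}

#' Pair-enumeration bookkeeping
#'
#' The combinatorial identities behind a pairwise correlation screen: a cross
#' of two feature sets enumerates `n_a * n_b` pairs; a self-cross enumerates
#' `n_a^2`, loses `n_a` self-pairs, and halves to `n_a * (n_a - 1) / 2`
#' unique unordered pairs after symmetric dedup. [build_network()] reports
#' exactly these counts.
#'
#' @param n_a Size of the (first) feature set.
#' @param n_b Size of the second set, or `NULL` for a self-cross.
#' @return List with `n_enumerated`, `n_self_removed`, `n_after_self`,
#'   `n_after_dedup`.
#' @export
enumerate_pair_counts <- function(n_a, n_b = NULL) {
  n_a <- as.numeric(n_a)
  if (is.null(n_b)) {
    list(n_enumerated = n_a * n_a,
         n_self_removed = n_a,
         n_after_self = n_a * n_a - n_a,
         n_after_dedup = n_a * (n_a - 1) / 2)
  } else {
    n_b <- as.numeric(n_b)
    list(n_enumerated = n_a * n_b, n_self_removed = 0,
         n_after_self = n_a * n_b, n_after_dedup = n_a * n_b)
  }
}

#' Collapse symmetric duplicate pair records
#'
#' A self-cross correlation lists every unordered pair twice (A-B and B-A);
#' this keeps one record per unordered pair (with `a_id < b_id`) and drops
#' self-pairs.
#'
#' @param pairs Data frame with `a_id` and `b_id` columns.
#' @return The deduplicated data frame.
#' @export
collapse_symmetric_pairs <- function(pairs) {
  pairs <- pairs[pairs$a_id != pairs$b_id, , drop = FALSE]
  lo <- pmin(pairs$a_id, pairs$b_id)
  hi <- pmax(pairs$a_id, pairs$b_id)
  keep <- !duplicated(paste(lo, hi, sep = "\r"))
  out <- pairs[keep, , drop = FALSE]
  out$a_id <- lo[keep]; out$b_id <- hi[keep]
  rownames(out) <- NULL
  out
}
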