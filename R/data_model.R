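#' Pipeline configuration
#'
#' Central container for every tunable threshold of the analysis. Defaults are
#' the study-stage values used throughout the glioblastoma lncRNA landscape
#' analysis: a +/-500 kb genomic window for cis pairs, a 1 kb TSS-to-TSS window
#' for bidirectional lncRNA calls, stage-specific fold-change cutoffs, raw
#' p < 0.05 for correlation filtering with an additional |rho| > 0.9 screen for
#' trans pairs, detectability in at least 30% of samples for survival
#' eligibility, and p < 0.05 for the sponge abundance test.
#'
#' @param cis_window Window, in bp, on either side of a lncRNA gene span within
#'   which a partner gene is called cis (inclusive boundary).
#' @param bidirectional_tss_window Maximum TSS-to-TSS distance, in bp, for a
#'   divergent (bidirectional) lncRNA call (inclusive).
#' @param de_fc_threshold Linear-scale fold-change cutoff for differential
#'   expression (applied as `|log2 FC| >= log2(de_fc_threshold)`).
#' @param de_p_threshold Raw p-value cutoff for differential expression.
#' @param de_fdr_threshold Benjamini-Hochberg FDR cutoff, used when
#'   `de_use_fdr = TRUE`.
#' @param de_use_fdr Logical; gate differential calls on FDR instead of raw p.
#' @param de_var_equal Logical; pooled-variance t-test instead of Welch.
#' @param corr_p_threshold Raw p-value cutoff for correlation pair filtering.
#' @param trans_abs_rho_threshold Additional absolute Spearman rho cutoff
#'   applied only to trans pairs.
#' @param expression_presence_fraction Fraction of samples in which a feature
#'   must be detected (value > 0) to enter the survival screen.
#' @param abundance_test_p P-value cutoff for the sponge-module lncRNA-vs-mRNA
#'   abundance test.
#' @param abundance_test One of `"wilcoxon"` (paired one-sided signed-rank,
#'   default) or `"t"` (paired one-sided t-test).
#' @param rng_seed Integer seed used by the synthetic-data generator.
#'
#' @return A list of class `"pipeline_config"`.
#' @examples
#' cfg <- pipeline_config(de_fc_threshold = 2)
#' cfg$cis_window
#' @export
pipeline_config <- function(cis_window = 500000L,
                            bidirectional_tss_window = 1000L,
                            de_fc_threshold = 1.5,
                            de_p_threshold = 0.05,
                            de_fdr_threshold = 0.05,
                            de_use_fdr = FALSE,
                            de_var_equal = FALSE,
                            corr_p_threshold = 0.05,
                            trans_abs_rho_threshold = 0.9,
                            expression_presence_fraction = 0.30,
                            abundance_test_p = 0.05,
                            abundance_test = c("wilcoxon", "t"),
                            rng_seed = 1L) {
  abundance_test <- match.arg(abundance_test)
  cfg <- list(
    cis_window = as.integer(cis_window),
    bidirectional_tss_window = as.integer(bidirectional_tss_window),
    de_fc_threshold = de_fc_threshold,
    de_p_threshold = de_p_threshold,
    de_fdr_threshold = de_fdr_threshold,
    de_use_fdr = isTRUE(de_use_fdr),
    de_var_equal = isTRUE(de_var_equal),
    corr_p_threshold = corr_p_threshold,
    trans_abs_rho_threshold = trans_abs_rho_threshold,
    expression_presence_fraction = expression_presence_fraction,
    abundance_test_p = abundance_test_p,
    abundance_test = abundance_test,
    rng_seed = as.integer(rng_seed)
  )
  thr <- c("de_fc_threshold", "de_p_threshold", "de_fdr_threshold",
           "corr_p_threshold", "trans_abs_rho_threshold", "abundance_test_p")
  for (nm in thr) {
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1L || cfg[[nm]] <= 0)
      stop(sprintf("'%s' must be a positive scalar", nm))
  }
  if (cfg$expression_presence_fraction <= 0 || cfg$expression_presence_fraction > 1)
    stop("'expression_presence_fraction' must lie in (0, 1]")
  if (cfg$cis_window < 0L || cfg$bidirectional_tss_window < 0L)
    stop("window sizes must be >= 0")
  structure(cfg, class = "pipeline_config")
}

#' Build a gene annotation table
#'
#' Assembles per-gene genomic annotation into the package's internal
#' representation: a data frame with one row per gene and an `exons`
#' list-column. All coordinates are 0-based half-open (BED convention);
#' dialect conversion happens only in [read_annotation()].
#'
#' @param gene_id,chrom Character vectors.
#' @param start,end Integer vectors, 0-based half-open.
#' @param strand Character vector of `"+"`/`"-"`.
#' @param biotype One of `"mRNA"`, `"lncRNA"`, `"miRNA"` per gene.
#' @param symbol Optional display symbol; defaults to `gene_id`.
#' @param exons Optional list of two-column matrices (start, end) per gene,
#'   same coordinate convention; defaults to the single full span.
#'
#' @return A `gene_annotation` data frame with columns `gene_id`, `symbol`,
#'   `chrom`, `start`, `end`, `strand`, `biotype`, `exons`.
#' @export
gene_annotation <- function(gene_id, chrom, start, end, strand, biotype,
                            symbol = gene_id, exons = NULL) {
  n <- length(gene_id)
  start <- as.integer(start); end <- as.integer(end)
  stopifnot(length(chrom) == n, length(start) == n, length(end) == n,
            length(strand) == n, length(biotype) %in% c(1L, n))
  if (length(biotype) == 1L) biotype <- rep(biotype, n)
  if (anyDuplicated(gene_id))
    stop("duplicate gene_id in annotation: ",
         paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "))
  if (any(start >= end)) stop("annotation with start >= end: ",
                              paste(gene_id[start >= end], collapse = ", "))
  if (!all(strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (!all(biotype %in% c("mRNA", "lncRNA", "miRNA")))
    stop("biotype must be one of mRNA, lncRNA, miRNA")
  if (is.null(exons)) {
    exons <- lapply(seq_len(n), function(i) cbind(start = start[i], end = end[i]))
  }
  stopifnot(length(exons) == n)
  for (i in seq_len(n)) {
    ex <- exons[[i]]
    if (!is.matrix(ex) || ncol(ex) != 2L)
      stop("exons must be two-column matrices")
    storage.mode(ex) <- "integer"
    colnames(ex) <- c("start", "end")
    ex <- ex[order(ex[, 1L]), , drop = FALSE]
    if (any(ex[, 1L] >= ex[, 2L])) stop("exon with start >= end in ", gene_id[i])
    if (nrow(ex) > 1L && any(ex[-1L, 1L] < ex[-nrow(ex), 2L]))
      stop("overlapping exons in ", gene_id[i])
    if (ex[1L, 1L] < start[i] || ex[nrow(ex), 2L] > end[i])
      stop("exon outside gene span in ", gene_id[i])
    exons[[i]] <- ex
  }
  out <- data.frame(gene_id = as.character(gene_id),
                    symbol = as.character(symbol),
                    chrom = as.character(chrom),
                    start = start, end = end,
                    strand = as.character(strand),
                    biotype = as.character(biotype),
                    stringsAsFactors = FALSE)
  out$exons <- exons
  class(out) <- c("gene_annotation", "data.frame")
  out
}

#' Build an expression matrix object
#'
#' @param values Numeric feature x sample matrix with row and column names
#'   (log2 intensities or linear counts).
#' @param groups Named character vector mapping every sample id to `"tumor"`
#'   or `"control"`.
#' @param scale `"log2"` or `"linear_count"`.
#' @param flags Optional character matrix of detection calls
#'   (`"P"`resent / `"M"`arginal / `"A"`bsent), same dimnames as `values`.
#'
#' @return An object of class `"expression_matrix"`.
#' @export
expression_matrix <- function(values, groups,
                              scale = c("log2", "linear_count"),
                              flags = NULL) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must carry feature rownames and sample colnames")
  if (anyDuplicated(rownames(values))) stop("duplicate feature ids")
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids")
  if (any(!is.finite(values))) stop("non-finite expression values")
  missing_grp <- setdiff(colnames(values), names(groups))
  if (length(missing_grp))
    stop("samples without a group label: ", paste(missing_grp, collapse = ", "))
  groups <- groups[colnames(values)]
  if (!all(groups %in% c("tumor", "control")))
    stop("group labels must be 'tumor' or 'control'")
  if (!is.null(flags)) {
    if (!identical(dim(flags), dim(values)) ||
        !identical(dimnames(flags), dimnames(values)))
      stop("'flags' must share dimnames with 'values'")
    if (!all(flags %in% c("P", "M", "A", "Present", "Marginal", "Absent")))
      stop("flags must be Present/Marginal/Absent (or P/M/A)")
  }
  structure(list(values = values, groups = groups, scale = scale, flags = flags),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d features x %d samples (%s scale)\n",
              nrow(x$values), ncol(x$values), x$scale))
  cat(sprintf("  groups: %d tumor, %d control; flags: %s\n",
              sum(x$groups == "tumor"), sum(x$groups == "control"),
              if (is.null(x$flags)) "absent" else "present"))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Subset an expression matrix by features and/or samples
#'
#' @param x An `expression_matrix`.
#' @param features,samples Character vectors of ids to keep (default all).
#' @return An `expression_matrix` restricted to the requested ids.
#' @export
subset_expression <- function(x, features = rownames(x$values),
                              samples = colnames(x$values)) {
  stopifnot(inherits(x, "expression_matrix"))
  missing_f <- setdiff(features, rownames(x$values))
  if (length(missing_f))
    stop("features absent from matrix: ", paste(missing_f, collapse = ", "))
  missing_s <- setdiff(samples, colnames(x$values))
  if (length(missing_s))
    stop("samples absent from matrix: ", paste(missing_s, collapse = ", "))
  expression_matrix(x$values[features, samples, drop = FALSE],
                    x$groups[samples], x$scale,
                    flags = if (!is.null(x$flags))
                      x$flags[features, samples, drop = FALSE])
}

#' Build an interaction table
#'
#' Pairwise regulatory interactions (e.g. predicted lncRNA->miRNA target pairs
#' in the miRcode style, or validated miRNA->mRNA pairs in the miRWalk style).
#' Duplicate (source, target) rows are collapsed; evidence is a property of the
#' table, not the row.
#'
#' @param source_id,target_id Character vectors of equal length.
#' @param evidence `"predicted"` or `"validated"`.
#' @param origin Free-text provenance tag.
#' @return A data frame of class `"interaction_table"` with attributes
#'   `evidence` and `origin`.
#' @export
interaction_table <- function(source_id, target_id,
                              evidence = c("predicted", "validated"),
                              origin = "unspecified") {
  evidence <- match.arg(evidence)
  stopifnot(length(source_id) == length(target_id))
  df <- unique(data.frame(source_id = as.character(source_id),
                          target_id = as.character(target_id),
                          stringsAsFactors = FALSE))
  rownames(df) <- NULL
  attr(df, "evidence") <- evidence
  attr(df, "origin") <- origin
  class(df) <- c("interaction_table", "data.frame")
  df
}

#' Build a survival record table
#'
#' @param sample_id Character vector of sample ids.
#' @param time Positive follow-up times (months).
#' @param event 1 = death observed, 0 = censored.
#' @param covariates Optional data frame of per-sample covariates (e.g.
#'   `age`, `g_cimp`, `idh1`, `mgmt`).
#' @return A data frame of class `"survival_table"`.
#' @export
survival_table <- function(sample_id, time, event, covariates = NULL) {
  n <- length(sample_id)
  stopifnot(length(time) == n, length(event) == n)
  if (anyDuplicated(sample_id)) stop("duplicate sample ids in survival table")
  if (any(time <= 0)) stop("survival times must be positive")
  if (!all(event %in% c(0, 1))) stop("event must be 0 (censored) or 1 (death)")
  df <- data.frame(sample_id = as.character(sample_id),
                   time = as.numeric(time), event = as.integer(event),
                   stringsAsFactors = FALSE)
  if (!is.null(covariates)) {
    stopifnot(nrow(covariates) == n)
    df <- cbind(df, covariates)
  }
  class(df) <- c("survival_table", "data.frame")
  df
}

# internal: covariate columns of a survival_table
surv_covariate_names <- function(surv) {
  setdiff(colnames(surv), c("sample_id", "time", "event"))
}
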