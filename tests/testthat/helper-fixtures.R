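# shared fixture builders; everything is generated in code

# minimal expression matrix: features x samples with half tumor / half control
toy_matrix <- function(values, n_tumor = NULL, scale = "log2", flags = NULL) {
  if (is.null(n_tumor)) n_tumor <- ceiling(ncol(values) / 2)
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("f%02d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  groups <- stats::setNames(
    rep(c("tumor", "control"), c(n_tumor, ncol(values) - n_tumor)),
    colnames(values))
  expression_matrix(values, groups, scale, flags)
}

# one mRNA gene with explicit exons (0-based half-open)
toy_gene <- function(id, chrom, exons, strand, biotype = "mRNA") {
  ex <- matrix(as.integer(unlist(exons)), ncol = 2, byrow = TRUE,
               dimnames = list(NULL, c("start", "end")))
  gene_annotation(gene_id = id, chrom = chrom,
                  start = min(ex[, 1]), end = max(ex[, 2]),
                  strand = strand, biotype = biotype, exons = list(ex))
}

# single-exon annotation row
toy_span <- function(id, chrom, start, end, strand, biotype = "lncRNA") {
  gene_annotation(gene_id = id, chrom = chrom, start = start, end = end,
                  strand = strand, biotype = biotype)
}

bind_ann <- function(...) {
  parts <- list(...)
  out <- do.call(rbind, lapply(parts, function(x) {
    class(x) <- "data.frame"
    x
  }))
  class(out) <- c("gene_annotation", "data.frame")
  rownames(out) <- NULL
  out
}

# brute-force interval overlap oracle over two annotation tables
brute_force_overlaps <- function(a, b, same_strand = TRUE) {
  out <- list()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] != b$chrom[j]) next
    if (same_strand && a$strand[i] != b$strand[j]) next
    s <- max(a$start[i], b$start[j]); e <- min(a$end[i], b$end[j])
    if (s < e)
      out[[length(out) + 1L]] <- data.frame(
        a_id = a$gene_id[i], b_id = b$gene_id[j],
        start = s, end = e, stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(a_id = character(0), b_id = character(0),
               start = integer(0), end = integer(0))
}

# DE table stub with declared directions (oracle-side construction)
stub_de <- function(ids, directions, log2_fc = NULL) {
  if (is.null(log2_fc))
    log2_fc <- ifelse(directions == "up", 2, ifelse(directions == "down", -2, 0))
  data.frame(feature_id = ids, mean_log2_tumor = 0, mean_log2_control = 0,
             log2_fc = log2_fc, p_value = 0.001, fdr = 0.001,
             direction = directions, stringsAsFactors = FALSE)
}
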