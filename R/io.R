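# Readers and writers. All dialect conversion to/from the internal 0-based
# half-open coordinate convention happens here and nowhere else.

#' Default biotype mapping for annotation import
#'
#' Maps common GTF/GFF3 biotype attribute values onto the three internal
#' classes. Gencode-style lncRNA classes (lincRNA, antisense,
#' processed_transcript, ...) all collapse onto `"lncRNA"`; the mapping is
#' user-replaceable because vendor annotations differ in which classes they
#' call long non-coding.
#'
#' @return Named character vector: source biotype -> internal biotype.
#' @export
default_biotype_map <- function() {
  c(protein_coding = "mRNA", mRNA = "mRNA",
    lncRNA = "lncRNA", lincRNA = "lncRNA", antisense = "lncRNA",
    processed_transcript = "lncRNA", sense_intronic = "lncRNA",
    sense_overlapping = "lncRNA", non_coding = "lncRNA",
    bidirectional_promoter_lncRNA = "lncRNA",
    miRNA = "miRNA")
}

#' Read gene annotation from GTF, GFF3 or BED12
#'
#' Parses an annotation file and converts coordinates into the internal
#' 0-based half-open convention (GTF/GFF3 1-based inclusive starts are shifted
#' down by one; BED passes through). For GTF/GFF3, `gene` records define the
#' spans and `exon` records the exon structure, grouped by `gene_id`; a file
#' with only exon records derives gene spans as the exon-union span. For
#' BED12, blocks become exons.
#'
#' @param path File path.
#' @param format `"GTF"`, `"GFF3"` or `"BED12"`.
#' @param biotype_map Named character vector mapping source biotype strings to
#'   `mRNA`/`lncRNA`/`miRNA`; see [default_biotype_map()].
#' @param unknown_biotype `"drop"` (default; warn and exclude) or `"mRNA"`
#'   (warn and keep as mRNA).
#' @param bed_biotype Biotype assigned to all records of a BED file, which
#'   carries no biotype column.
#'
#' @return A [gene_annotation()] data frame.
#' @export
read_annotation <- function(path, format = c("GTF", "GFF3", "BED12"),
                            biotype_map = default_biotype_map(),
                            unknown_biotype = c("drop", "mRNA"),
                            bed_biotype = "miRNA") {
  format <- match.arg(format)
  unknown_biotype <- match.arg(unknown_biotype)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (format %in% c("GTF", "GFF3")) {
    validate_tab_file(path, min_fields = 9L, comment = "#")
    gr <- rtracklayer::import(path, format = if (format == "GTF") "gtf" else "gff3")
    read_annotation_granges(gr, biotype_map, unknown_biotype)
  } else {
    bed <- rtracklayer::import(path, format = "bed")
    read_annotation_bed12(bed, bed_biotype)
  }
}

# light structural pre-scan so malformed lines fail with a line number
validate_tab_file <- function(path, min_fields, comment = NULL) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln)) next
    if (!is.null(comment) && startsWith(ln, comment)) next
    nf <- length(strsplit(ln, "\t", fixed = TRUE)[[1L]])
    if (nf < min_fields)
      stop(sprintf("malformed line %d in %s: %d field(s), expected >= %d",
                   i, path, nf, min_fields))
  }
  invisible(TRUE)
}

read_annotation_granges <- function(gr, biotype_map, unknown_biotype) {
  md <- S4Vectors::mcols(gr)
  typ <- as.character(md$type)
  gene_id <- as.character(md$gene_id)
  if (all(is.na(gene_id))) stop("annotation lacks gene_id attributes")
  src_bio <- rep(NA_character_, length(gr))
  for (col in c("gene_biotype", "gene_type", "biotype")) {
    if (col %in% colnames(md)) {
      v <- as.character(md[[col]])
      src_bio[is.na(src_bio)] <- v[is.na(src_bio)]
    }
  }
  sym <- if ("gene_name" %in% colnames(md)) as.character(md$gene_name) else gene_id

  is_gene <- typ == "gene"
  if (!any(is_gene)) is_gene <- typ %in% c("transcript", "mRNA")
  is_exon <- typ == "exon"
  ids <- unique(gene_id[is_gene | is_exon])
  ids <- ids[!is.na(ids)]

  rec <- lapply(ids, function(id) {
    gi <- which(is_gene & gene_id == id)
    ei <- which(is_exon & gene_id == id)
    span_rows <- if (length(gi)) gi else ei
    st <- min(GenomicRanges::start(gr)[span_rows]) - 1L  # to 0-based
    en <- max(GenomicRanges::end(gr)[span_rows])
    ex <- if (length(ei)) {
      m <- cbind(start = GenomicRanges::start(gr)[ei] - 1L,
                 end = GenomicRanges::end(gr)[ei])
      merge_overlapping_intervals(m[order(m[, 1L]), , drop = FALSE])
    } else cbind(start = st, end = en)
    list(id = id,
         symbol = sym[span_rows[1L]],
         chrom = as.character(GenomicRanges::seqnames(gr))[span_rows[1L]],
         start = st, end = en,
         strand = as.character(GenomicRanges::strand(gr))[span_rows[1L]],
         src_bio = src_bio[span_rows[1L]],
         exons = m_or(ex))
  })
  src <- vapply(rec, `[[`, "", "src_bio")
  mapped <- unname(biotype_map[src])
  unknown <- is.na(mapped)
  if (any(unknown)) {
    warning("unknown biotype(s) ",
            paste(unique(src[unknown]), collapse = ", "),
            if (unknown_biotype == "drop") " - records dropped"
            else " - kept as mRNA")
    if (unknown_biotype == "mRNA") mapped[unknown] <- "mRNA"
    else { rec <- rec[!unknown]; mapped <- mapped[!unknown] }
  }
  if (!length(rec)) stop("no annotation records survived biotype mapping")
  gene_annotation(
    gene_id = vapply(rec, `[[`, "", "id"),
    symbol = vapply(rec, `[[`, "", "symbol"),
    chrom = vapply(rec, `[[`, "", "chrom"),
    start = vapply(rec, function(r) r$start, 0L),
    end = vapply(rec, function(r) r$end, 0L),
    strand = vapply(rec, `[[`, "", "strand"),
    biotype = mapped,
    exons = lapply(rec, `[[`, "exons"))
}

m_or <- function(ex) { storage.mode(ex) <- "integer"; ex }

# union of strictly overlapping sorted intervals (adjacent ones kept distinct,
# so exon structure written by this package round-trips unchanged)
merge_overlapping_intervals <- function(m) {
  if (nrow(m) < 2L) return(m)
  out <- m[1L, , drop = FALSE]
  for (i in 2L:nrow(m)) {
    k <- nrow(out)
    if (m[i, 1L] < out[k, 2L]) {
      out[k, 2L] <- max(out[k, 2L], m[i, 2L])
    } else if (m[i, 1L] == out[k, 1L] && m[i, 2L] == out[k, 2L]) {
      next
    } else out <- rbind(out, m[i, , drop = FALSE])
  }
  out
}

read_annotation_bed12 <- function(bed, bed_biotype) {
  st <- GenomicRanges::start(bed) - 1L  # rtracklayer presents BED as 1-based
  en <- GenomicRanges::end(bed)
  nm <- S4Vectors::mcols(bed)$name
  if (is.null(nm)) nm <- paste0("feature_", seq_along(bed))
  blocks <- S4Vectors::mcols(bed)$blocks
  exons <- if (is.null(blocks)) NULL else lapply(seq_along(bed), function(i) {
    b <- blocks[[i]]
    cbind(start = st[i] + IRanges::start(b) - 1L,
          end = st[i] + IRanges::end(b))
  })
  gene_annotation(gene_id = as.character(nm),
                  chrom = as.character(GenomicRanges::seqnames(bed)),
                  start = st, end = en,
                  strand = as.character(GenomicRanges::strand(bed)),
                  biotype = bed_biotype, exons = exons)
}

#' Write gene annotation as GTF
#'
#' Emits one `gene` line and one `exon` line per exon, converting internal
#' 0-based half-open coordinates back to GTF's 1-based inclusive convention,
#' so that `read_annotation(write_annotation_gtf(x))` round-trips exactly.
#'
#' @param ann A [gene_annotation()] table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation_gtf <- function(ann, path) {
  stopifnot(inherits(ann, "gene_annotation"))
  lines <- character(0)
  for (i in seq_len(nrow(ann))) {
    attrs <- sprintf('gene_id "%s"; gene_name "%s"; gene_biotype "%s";',
                     ann$gene_id[i], ann$symbol[i],
                     c(mRNA = "protein_coding", lncRNA = "lncRNA",
                       miRNA = "miRNA")[[ann$biotype[i]]])
    lines <- c(lines,
               paste(ann$chrom[i], "lncscape", "gene",
                     ann$start[i] + 1L, ann$end[i], ".", ann$strand[i], ".",
                     attrs, sep = "\t"))
    ex <- ann$exons[[i]]
    for (j in seq_len(nrow(ex))) {
      lines <- c(lines,
                 paste(ann$chrom[i], "lncscape", "exon",
                       ex[j, 1L] + 1L, ex[j, 2L], ".", ann$strand[i], ".",
                       attrs, sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write annotation as BED6
#'
#' @param ann A [gene_annotation()] table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation_bed6 <- function(ann, path) {
  stopifnot(inherits(ann, "gene_annotation"))
  df <- data.frame(ann$chrom, ann$start, ann$end, ann$gene_id, 0L, ann$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read miRNA (or other) coordinates from BED6
#'
#' @param path BED6 file path (0-based half-open, miRBase dialect).
#' @param biotype Biotype assigned to all records.
#' @return A [gene_annotation()] table.
#' @export
read_bed6 <- function(path, biotype = "miRNA") {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(df) < 6L) stop("BED6 requires 6 columns, found ", ncol(df))
  gene_annotation(gene_id = df[[4L]], chrom = df[[1L]],
                  start = df[[2L]], end = df[[3L]],
                  strand = df[[6L]], biotype = biotype)
}

#' Read an expression matrix with its sample sheet
#'
#' The matrix TSV has a header row of sample ids and feature ids in the first
#' column. The sample sheet TSV must have columns `sample_id` and `group`
#' (`tumor`/`control`) covering every matrix column.
#'
#' @param path Matrix TSV path.
#' @param sample_sheet Sample sheet TSV path.
#' @param scale `"log2"` or `"linear_count"`.
#' @param flags_path Optional TSV of detection flags with the same layout.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, sample_sheet,
                            scale = c("log2", "linear_count"),
                            flags_path = NULL) {
  scale <- match.arg(scale)
  raw <- utils::read.table(path, sep = "\t", header = TRUE, row.names = NULL,
                           check.names = FALSE, stringsAsFactors = FALSE)
  feat <- as.character(raw[[1L]])
  if (anyDuplicated(feat))
    stop("duplicate feature id(s): ",
         paste(unique(feat[duplicated(feat)]), collapse = ", "))
  m <- raw[, -1L, drop = FALSE]
  for (j in seq_along(m)) {
    if (!is.numeric(m[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(m[[j]]))))[1L]
      stop(sprintf("non-numeric cell at feature '%s', sample '%s'",
                   feat[bad], colnames(m)[j]))
    }
  }
  m <- as.matrix(m)
  rownames(m) <- feat
  sheet <- utils::read.table(sample_sheet, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% colnames(sheet)))
    stop("sample sheet needs columns 'sample_id' and 'group'")
  groups <- stats::setNames(sheet$group, sheet$sample_id)
  flags <- NULL
  if (!is.null(flags_path)) {
    fr <- utils::read.table(flags_path, sep = "\t", header = TRUE,
                            row.names = 1L, check.names = FALSE,
                            stringsAsFactors = FALSE)
    flags <- as.matrix(fr)[rownames(m), colnames(m), drop = FALSE]
  }
  expression_matrix(m, groups, scale, flags)
}

#' Write an expression matrix (and optionally its sample sheet)
#'
#' @param m An [expression_matrix()].
#' @param path Matrix TSV path.
#' @param sample_sheet Optional sample sheet TSV path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path, sample_sheet = NULL) {
  stopifnot(inherits(m, "expression_matrix"))
  # %.17g preserves doubles exactly, so read_expression round-trips bitwise
  txt <- matrix(sprintf("%.17g", m$values), nrow(m$values))
  df <- data.frame(feature_id = rownames(m$values), txt,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("feature_id", colnames(m$values))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sample_sheet)) {
    utils::write.table(
      data.frame(sample_id = names(m$groups), group = unname(m$groups)),
      sample_sheet, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read an interaction table (miRcode/miRWalk-like TSV)
#'
#' First two columns are source and target ids; duplicates collapse.
#'
#' @param path TSV path with a header row.
#' @param evidence `"predicted"` or `"validated"`.
#' @param origin Provenance tag.
#' @return An [interaction_table()].
#' @export
read_interactions <- function(path, evidence = c("predicted", "validated"),
                              origin = basename(path)) {
  evidence <- match.arg(evidence)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("interaction table needs >= 2 columns")
  interaction_table(df[[1L]], df[[2L]], evidence = evidence, origin = origin)
}

#' Write an interaction table
#' @param tab An [interaction_table()].
#' @param path TSV output path.
#' @return `path`, invisibly.
#' @export
write_interactions <- function(tab, path) {
  utils::write.table(as.data.frame(tab), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read survival records from TSV
#'
#' Requires columns `sample_id`, `time`, `event`; any further columns are
#' treated as covariates.
#'
#' @param path TSV path.
#' @return A [survival_table()].
#' @export
read_survival <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "time", "event")
  if (!all(need %in% colnames(df)))
    stop("survival table needs columns: ", paste(need, collapse = ", "))
  cov <- df[, setdiff(colnames(df), need), drop = FALSE]
  survival_table(df$sample_id, df$time, df$event,
                 covariates = if (ncol(cov)) cov)
}

#' Write survival records to TSV
#' @param surv A [survival_table()].
#' @param path TSV output path.
#' @return `path`, invisibly.
#' @export
write_survival <- function(surv, path) {
  df <- as.data.frame(surv)
  df$time <- sprintf("%.17g", df$time)   # exact double round-trip
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write correlation pairs to TSV
#'
#' Column order: a_id, b_id, pair_kind, rho, p_value, fdr, distance_class,
#' quadrant, genomic_gap. An empty pair list yields a header-only file.
#'
#' @param pairs A correlation-pair data frame from [build_network()].
#' @param path TSV output path.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pairs, path) {
  cols <- c("a_id", "b_id", "pair_kind", "rho", "p_value", "fdr",
            "distance_class", "quadrant", "genomic_gap")
  df <- if (nrow(pairs)) pairs[, cols, drop = FALSE] else
    stats::setNames(as.data.frame(matrix(nrow = 0, ncol = length(cols))), cols)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read correlation pairs written by [write_pairs()]
#' @param path TSV path.
#' @return A data frame.
#' @export
read_pairs <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    colClasses = c(a_id = "character", b_id = "character"))
}

#' Write sponge modules to TSV
#' @param modules A sponge-module data frame from [filter_modules()].
#' @param path TSV output path.
#' @return `path`, invisibly.
#' @export
write_modules <- function(modules, path) {
  utils::write.table(modules, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export a pair list as a bare edge list for graph tools
#'
#' @param pairs A correlation-pair data frame.
#' @param path TSV output path (columns a_id, b_id, rho; no header).
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(pairs, path) {
  utils::write.table(pairs[, c("a_id", "b_id", "rho")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
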