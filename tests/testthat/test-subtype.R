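# positional subtype classification and the exon-overlap removal rule

# one plus-strand gene on chr1 with two exons and one intron
ref_gene <- function() toy_gene("G1", "chr1", list(c(10000, 11000),
                                                   c(20000, 21000)), "+")

test_that("each constructed geometry maps to its subtype", {
  g <- ref_gene()
  cfg <- pipeline_config()
  cases <- list(
    list(toy_span("L_eso", "chr1", 10500, 12000, "+"), "exon_sense_overlapping"),
    list(toy_span("L_nat", "chr1", 10500, 12000, "-"), "natural_antisense"),
    list(toy_span("L_iso", "chr1", 12000, 13000, "+"), "intron_sense_overlapping"),
    list(toy_span("L_ia", "chr1", 12000, 13000, "-"), "intronic_antisense"),
    list(toy_span("L_bid", "chr1", 6000, 9200, "-"), "bidirectional"),
    list(toy_span("L_int", "chr1", 900000, 905000, "+"), "intergenic"))
  for (cs in cases) {
    call <- classify_lncrnas(cs[[1]], g, cfg)
    expect_equal(call$subtype, cs[[2]], label = cs[[1]]$gene_id)
    if (cs[[2]] == "intergenic") expect_true(is.na(call$partner_gene_id))
    else expect_equal(call$partner_gene_id, "G1")
  }
})

test_that("minus-strand lncRNA inside the intron of a plus-strand gene is intronic antisense", {
  call <- classify_lncrnas(toy_span("L1", "chr1", 11500, 19500, "-"),
                           ref_gene(), pipeline_config())
  expect_equal(call$subtype, "intronic_antisense")
})

test_that("the bidirectional TSS window is inclusive at 1,000 bp", {
  g <- ref_gene()  # + strand, TSS at 10000
  cfg <- pipeline_config()
  # minus-strand lncRNA upstream; its TSS is its end coordinate
  at <- function(d) toy_span("L", "chr1", 10000 - d - 2000, 10000 - d, "-")
  expect_equal(classify_lncrnas(at(800), g, cfg)$subtype, "bidirectional")
  expect_equal(classify_lncrnas(at(1000), g, cfg)$subtype, "bidirectional")
  expect_equal(classify_lncrnas(at(1001), g, cfg)$subtype, "intergenic")
})

test_that("lncRNAs on chromosomes without mRNAs are intergenic with a warning", {
  expect_warning(
    call <- classify_lncrnas(toy_span("L1", "chrX", 100, 2000, "+"),
                             ref_gene(), pipeline_config()),
    "chrX")
  expect_equal(call$subtype, "intergenic")
})

test_that("flipping both strands leaves overlap-based calls unchanged", {
  cfg <- pipeline_config()
  g_plus <- ref_gene()
  g_minus <- toy_gene("G1", "chr1", list(c(10000, 11000), c(20000, 21000)), "-")
  spans <- list(c(10500, 12000), c(12000, 13000), c(11500, 19500))
  for (sp in spans) for (st in c("+", "-")) {
    a <- classify_lncrnas(toy_span("L", "chr1", sp[1], sp[2], st), g_plus, cfg)
    flip <- if (st == "+") "-" else "+"
    b <- classify_lncrnas(toy_span("L", "chr1", sp[1], sp[2], flip), g_minus, cfg)
    expect_equal(a$subtype, b$subtype)
  }
})

test_that("exon-overlap removal drops contained spans only, matching a brute-force oracle", {
  cfg <- pipeline_config()
  mrnas <- bind_ann(ref_gene(),
                    toy_gene("G2", "chr1", list(c(50000, 52000)), "-"))
  # 12 lncRNAs with mixed geometry
  set.seed(13)
  specs <- list(
    c(10100, 10900, 1), c(10500, 11500, 1), c(9000, 10500, 1),
    c(50100, 51000, 2), c(50100, 51000, 1), c(49000, 53000, 2),
    c(10100, 10900, 2), c(20010, 20500, 1), c(19000, 20500, 1),
    c(51000, 52500, 2), c(10000, 11000, 1), c(12000, 13000, 1))
  strands <- c("+", "-")
  lncs <- do.call(bind_ann, lapply(seq_along(specs), function(i) {
    s <- specs[[i]]
    toy_span(sprintf("L%02d", i), "chr1", s[1], s[2], strands[s[3]])
  }))
  calls <- classify_lncrnas(lncs, mrnas, cfg)
  res <- apply_exon_overlap_removal(calls, lncs, mrnas)

  # oracle: containment of the lncRNA span within the merged same-strand
  # exonic footprint
  oracle_removed <- vapply(seq_len(nrow(lncs)), function(i) {
    ex <- do.call(rbind, mrnas$exons[mrnas$strand == lncs$strand[i] &
                                       mrnas$chrom == lncs$chrom[i]])
    if (is.null(ex)) return(FALSE)
    any(apply(ex, 1, function(e)
      lncs$start[i] >= e[1] && lncs$end[i] <= e[2]))
  }, logical(1))
  expect_setequal(res$removed, lncs$gene_id[oracle_removed])
  # removal only applies to exon-sense-overlapping calls
  expect_true(all(res$calls$subtype[res$calls$removed_by_exon_rule] ==
                    "exon_sense_overlapping"))
})

test_that("subtype summary reproduces the reference percentages", {
  calls <- data.frame(
    lncrna_id = sprintf("L%05d", 1:7790),
    subtype = rep(c("intergenic", "natural_antisense"), c(4720, 3070)),
    partner_gene_id = NA_character_, removed_by_exon_rule = FALSE,
    stringsAsFactors = FALSE)
  s <- subtype_summary(calls)
  expect_equal(s$percentage[s$subtype == "intergenic"], 60.59)
  expect_equal(sum(s$count), 7790L)

  one <- subtype_summary(calls[1, , drop = FALSE])
  expect_equal(one$percentage[one$subtype == "intergenic"], 100)

  eq <- data.frame(lncrna_id = sprintf("L%d", 1:6),
                   subtype = c("intergenic", "intronic_antisense",
                               "intron_sense_overlapping", "natural_antisense",
                               "exon_sense_overlapping", "bidirectional"),
                   stringsAsFactors = FALSE)
  expect_equal(unique(subtype_summary(eq)$percentage), 16.67)
})

test_that("classification partitions the input and recovers planted labels exactly", {
  sim <- simulate_annotation(n_mrna = 30, n_lnc = 24, n_mirna = 4,
                             n_cis_pairs = 3, n_host = 2, seed = 17)
  ann <- sim$annotation
  lncs <- ann[ann$biotype == "lncRNA", ]
  mrnas <- ann[ann$biotype == "mRNA", ]
  calls <- classify_lncrnas(lncs, mrnas, pipeline_config())
  expect_equal(nrow(calls), nrow(lncs))
  expect_equal(sum(subtype_summary(calls)$count), nrow(lncs))
  expect_equal(stats::setNames(calls$subtype, calls$lncrna_id),
               sim$truth$subtype_of[calls$lncrna_id])
})
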