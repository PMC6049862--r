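# readers/writers and the internal coordinate convention

test_that("GTF import shifts 1-based inclusive coordinates to 0-based half-open", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(paste("chr1", "src", "gene", "101", "200", ".", "+", ".",
                   'gene_id "G1"; gene_biotype "protein_coding";',
                   sep = "\t"), gtf)
  ann <- read_annotation(gtf, "GTF")
  expect_equal(ann$start, 100L)
  expect_equal(ann$end, 200L)
  expect_equal(ann$biotype, "mRNA")
})

test_that("toy GTF spans match an independent line-by-line parser", {
  set.seed(42)
  ann0 <- simulate_annotation(n_mrna = 6, n_lnc = 6, n_mirna = 2,
                              n_cis_pairs = 1, n_host = 1, seed = 5)$annotation
  gtf <- tempfile(fileext = ".gtf")
  write_annotation_gtf(ann0, gtf)

  # oracle: naive text parsing of gene lines only
  lines <- readLines(gtf)
  f <- strsplit(lines, "\t", fixed = TRUE)
  gene_lines <- f[vapply(f, `[[`, "", 3) == "gene"]
  oracle <- data.frame(
    gene_id = sub('.*gene_id "([^"]+)".*', "\\1",
                  vapply(gene_lines, `[[`, "", 9)),
    start = as.integer(vapply(gene_lines, `[[`, "", 4)) - 1L,
    end = as.integer(vapply(gene_lines, `[[`, "", 5)),
    stringsAsFactors = FALSE)

  ann <- read_annotation(gtf, "GTF")
  m <- match(oracle$gene_id, ann$gene_id)
  expect_false(anyNA(m))
  expect_equal(ann$start[m], oracle$start)
  expect_equal(ann$end[m], oracle$end)
})

test_that("GTF round-trips exactly through the internal convention", {
  ann0 <- simulate_annotation(n_mrna = 8, n_lnc = 8, n_mirna = 3,
                              n_cis_pairs = 1, n_host = 1, seed = 9)$annotation
  g1 <- tempfile(fileext = ".gtf"); g2 <- tempfile(fileext = ".gtf")
  write_annotation_gtf(ann0, g1)
  ann1 <- read_annotation(g1, "GTF")
  m <- match(ann0$gene_id, ann1$gene_id)
  expect_equal(ann1$start[m], ann0$start)
  expect_equal(ann1$end[m], ann0$end)
  expect_equal(ann1$strand[m], ann0$strand)
  expect_equal(ann1$exons[m], ann0$exons, ignore_attr = TRUE)
  write_annotation_gtf(ann1[m, ], g2)
  expect_identical(readLines(g1), readLines(g2))
})

test_that("BED12 blocks become exons in ascending order", {
  bed <- tempfile(fileext = ".bed")
  # 2 blocks: sizes 100,150 at offsets 0,300 from chromStart 1000
  writeLines(paste("chr2", "1000", "1450", "LNCX", "0", "-",
                   "1000", "1450", "0", "2", "100,150,", "0,300,",
                   sep = "\t"), bed)
  ann <- read_annotation(bed, "BED12", bed_biotype = "lncRNA")
  expect_equal(ann$start, 1000L)
  expect_equal(ann$end, 1450L)
  ex <- ann$exons[[1]]
  expect_equal(unname(ex[, "start"]), c(1000L, 1300L))
  expect_equal(unname(ex[, "end"]), c(1100L, 1450L))
})

test_that("malformed annotation lines fail naming the line number", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(paste("chr1", "src", "gene", "1", "10", ".", "+", ".",
                     'gene_id "G1";', sep = "\t"),
               "chr1 only three fields"), gtf)
  expect_error(read_annotation(gtf, "GTF"), "line 2")
})

test_that("unknown biotypes warn and are dropped (or kept as mRNA)", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(paste("chr1", "s", "gene", "1", "10", ".", "+", ".",
                     'gene_id "G1"; gene_biotype "protein_coding";', sep = "\t"),
               paste("chr1", "s", "gene", "20", "30", ".", "+", ".",
                     'gene_id "G2"; gene_biotype "pseudogene";', sep = "\t")),
             gtf)
  expect_warning(ann <- read_annotation(gtf, "GTF"), "pseudogene")
  expect_equal(ann$gene_id, "G1")
  expect_warning(ann2 <- read_annotation(gtf, "GTF", unknown_biotype = "mRNA"))
  expect_setequal(ann2$gene_id, c("G1", "G2"))
})

test_that("expression matrices read, validate, and round-trip bitwise", {
  v <- matrix(rnorm(12), 3, 4,
              dimnames = list(c("fa", "fb", "fc"), paste0("s", 1:4)))
  em <- toy_matrix(v)
  mpath <- tempfile(); spath <- tempfile()
  write_expression(em, mpath, spath)
  back <- read_expression(mpath, spath)
  expect_equal(dim(back$values), c(3L, 4L))
  expect_identical(back$values, em$values)   # bitwise via full-precision TSV
  expect_identical(back$groups, em$groups)

  # sample sheet missing a sample
  sheet <- utils::read.table(spath, sep = "\t", header = TRUE)
  utils::write.table(sheet[-1, ], spath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(read_expression(mpath, spath), "without a group label")

  # duplicate feature ids
  dup <- rbind(c("fa", 1, 2, 3, 4), c("fa", 5, 6, 7, 8))
  dpath <- tempfile()
  writeLines(c(paste(c("feature_id", paste0("s", 1:4)), collapse = "\t"),
               apply(dup, 1, paste, collapse = "\t")), dpath)
  utils::write.table(sheet, spath, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_expression(dpath, spath), "duplicate feature")

  # non-numeric cell named
  bad <- c(paste(c("feature_id", paste0("s", 1:4)), collapse = "\t"),
           paste(c("fa", "1", "oops", "3", "4"), collapse = "\t"))
  bpath <- tempfile(); writeLines(bad, bpath)
  expect_error(read_expression(bpath, spath), "fa")
})

test_that("pair and module writers handle empty, small, and round-trip cases", {
  empty <- data.frame(a_id = character(0), b_id = character(0),
                      pair_kind = character(0), rho = numeric(0),
                      p_value = numeric(0), fdr = numeric(0),
                      distance_class = character(0), quadrant = character(0),
                      genomic_gap = integer(0))
  p1 <- tempfile()
  write_pairs(empty, p1)
  expect_length(readLines(p1), 1L)   # header only

  pairs <- data.frame(
    a_id = sprintf("L%02d", 1:10), b_id = sprintf("M%02d", 1:10),
    pair_kind = "lnc_mrna", rho = round(seq(-0.9, 0.9, length.out = 10), 6),
    p_value = round(seq(0.001, 0.05, length.out = 10), 6),
    fdr = round(seq(0.01, 0.2, length.out = 10), 6),
    distance_class = rep(c("cis", "trans"), 5),
    quadrant = "up_up", genomic_gap = c(1:9 * 1000L, NA),
    stringsAsFactors = FALSE)
  p2 <- tempfile()
  write_pairs(pairs[1:2, ], p2)
  expect_length(readLines(p2), 3L)   # header + 2 rows
  write_pairs(pairs, p2)
  expect_equal(read_pairs(p2), pairs)
})

test_that("interaction tables collapse duplicates; survival tables validate", {
  tab <- interaction_table(c("L1", "L1", "L2"), c("m1", "m1", "m1"),
                           evidence = "predicted")
  expect_equal(nrow(tab), 2L)
  expect_equal(attr(tab, "evidence"), "predicted")

  expect_error(survival_table("s1", -1, 1), "positive")
  expect_error(survival_table("s1", 5, 2), "event")
  expect_error(survival_table(c("s1", "s1"), c(1, 2), c(0, 1)), "duplicate")
  sv <- survival_table(c("s1", "s2"), c(3.5, 10), c(1, 0),
                       covariates = data.frame(age = c(60, 55)))
  st <- tempfile()
  write_survival(sv, st)
  expect_equal(as.data.frame(read_survival(st)), as.data.frame(sv))
})
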