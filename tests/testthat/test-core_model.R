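test_that("read_fasta parses, normalizes and round-trips", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">c1", "ACGT"), f)
  expect_identical(read_fasta(f), c(c1 = "ACGT"))

  writeLines(c(">c1", "acgt"), f)
  expect_identical(read_fasta(f), c(c1 = "ACGT"))

  seqs <- c(a = "ACGTACGTNN", b = "GGGCCC")
  write_fasta(seqs, f)
  expect_identical(read_fasta(f), seqs)

  writeLines(c("ACGT", ">x", "ACGT"), f)
  expect_error(read_fasta(f), "header")
  writeLines(c(">c1", "ACWT"), f)   # IUPAC-ambiguous base, not plain ACGTN
  expect_error(read_fasta(f), "non-ACGTN")
})

test_that("read_gff3 converts coordinates and enforces invariants", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t101\t160\t.\t+\t.\tID=g1;locus_tag=tst_00005",
               "chr1\tsrc\tgene\t300\t500\t.\t-\t.\tID=g2;locus_tag=tst_00010"),
             f)
  ann <- read_gff3(f)
  expect_equal(ann$start, c(100L, 299L))
  expect_equal(ann$end, c(160L, 500L))
  expect_equal(ann$strand, c("+", "-"))

  # feature without locus_tag is skipped with a warning
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t101\t160\t.\t+\t.\tID=g1;locus_tag=tst_00005",
               "chr1\tsrc\tgene\t300\t500\t.\t-\t.\tID=anon"), f)
  expect_warning(ann2 <- read_gff3(f), "locus_tag")
  expect_equal(nrow(ann2), 1L)

  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t101\t160\t.\t+\t.\tlocus_tag=tst_00005",
               "chr1\tsrc\tgene\t300\t500\t.\t-\t.\tlocus_tag=tst_00005"), f)
  expect_error(read_gff3(f), "duplicate")
})

test_that("gene annotation round-trips through the GFF3 writer", {
  ann <- mk_annotation(c(100, 1000, 2500), c(300, 600, 200),
                       c("+", "-", "+"))
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(ann, f)
  back <- read_gff3(f)
  expect_equal(back$start, ann$start)
  expect_equal(back$end, ann$end)
  expect_equal(back$strand, ann$strand)
  expect_equal(back$locus_tag, ann$locus_tag)
})

test_that("read_narrowpeak summit arithmetic, fallback and validation", {
  f <- withr::local_tempfile(fileext = ".narrowPeak")
  writeLines(c("chr1\t500\t1550\tp1\t100\t.\t2.5\t10\t8\t300",
               "chr1\t100\t300\tp2\t50\t.\t1.2\t5\t3\t-1"), f)
  expect_warning(pk <- read_narrowpeak(f), "midpoint")
  expect_equal(pk$summit, c(800L, 200L))
  expect_equal(pk$fold_enrichment, c(2.5, 1.2))
  expect_equal(pk$neg_log10_q, c(8, 3))

  writeLines("chr1\t500\t1550\tp1\t100\t.\t2.5\t10\t8", f)
  expect_error(read_narrowpeak(f), "10 columns")

  writeLines("chr1\t500\t1550\tp1\t100\t.\t2.5\t10\t8\t2000", f)
  expect_error(read_narrowpeak(f), "outside")
})

test_that("promoter_window is strand-aware, clipped, and length-stable", {
  cfg <- pipeline_config()
  ann <- mk_annotation(c(1000, 1600, 100), c(500, 400, 200),
                       c("+", "-", "+"))
  w <- promoter_window(ann, cfg, chrom_len = 1e6L)
  # + strand: [start-350, start+50)
  expect_equal(c(w$start[1], w$end[1]), c(650L, 1050L))
  # - strand gene with end 2000: [1950, 2350)
  expect_equal(c(w$start[2], w$end[2]), c(1950L, 2350L))
  # clipped at chromosome start
  expect_equal(c(w$start[3], w$end[3]), c(0L, 150L))

  # property: unclipped windows have length upstream + downstream; clipping
  # only shortens
  set.seed(42)
  for (i in 1:20) {
    starts <- sort(sample(400:9000, 5))
    ann_i <- mk_annotation(starts, rep(300, 5),
                           sample(c("+", "-"), 5, replace = TRUE))
    w_i <- promoter_window(ann_i, cfg, chrom_len = 10000L)
    len <- w_i$end - w_i$start
    expect_true(all(len <= cfg$promoter_upstream + cfg$promoter_downstream))
    inner <- w_i$start > 0 & w_i$end < 10000
    expect_true(all(len[inner] ==
                      cfg$promoter_upstream + cfg$promoter_downstream))
  }
  expect_error(promoter_window(ann, cfg, chrom_len = 1500L), "outside")
})

test_that("infer_operons joins by gap and strand and partitions genes", {
  cfg <- pipeline_config()
  # gaps 10 and 20 -> one 3-gene operon
  a <- mk_annotation(c(0, 310, 630), c(300, 300, 300), rep("+", 3))
  ops <- infer_operons(a, cfg)
  expect_length(ops, 1)
  expect_equal(as.character(ops[[1]]), a$locus_tag)

  # gaps 10 and 80 -> 2-gene operon plus singleton
  b <- mk_annotation(c(0, 310, 690), c(300, 300, 300), rep("+", 3))
  ops <- infer_operons(b, cfg)
  expect_length(ops, 1)
  expect_equal(as.character(ops[[1]]), b$locus_tag[1:2])

  # alternating strands -> no operons
  d <- mk_annotation(c(0, 310, 630), c(300, 300, 300), c("+", "-", "+"))
  expect_length(infer_operons(d, cfg), 0)

  # minus-strand operon is reported 5'->3' on the coding strand
  e <- mk_annotation(c(0, 310), c(300, 300), c("-", "-"))
  expect_equal(as.character(infer_operons(e, cfg)[[1]]),
               rev(e$locus_tag))

  # property: operons partition their genes (no duplicates) on random input
  set.seed(7)
  for (i in 1:10) {
    n <- 30
    starts <- cumsum(sample(c(5:45, 300:500), n, replace = TRUE)) + 1:n * 200
    f <- mk_annotation(starts, rep(180, n),
                       sample(c("+", "-"), n, replace = TRUE))
    members <- unlist(infer_operons(f, cfg))
    expect_false(anyDuplicated(members) > 0)
  }
})

test_that("genes_in_locus_range reproduces step-5 range counts", {
  ann <- mk_step5_annotation("vnz", 4355, 4560)
  expect_equal(nrow(genes_in_locus_range("vnz_04355", "vnz_04560", ann)), 42L)

  ann1 <- mk_step5_annotation("vnz", 1060, 1105)
  expect_equal(nrow(genes_in_locus_range("vnz_01060", "vnz_01105", ann1)), 10L)

  expect_equal(nrow(genes_in_locus_range("vnz_04355", "vnz_04355", ann)), 1L)
  expect_error(genes_in_locus_range("vnz_04560", "vnz_04355", ann),
               "reversed")
  # property: step-5 annotation gives (last - first)/5 + 1 genes
  set.seed(3)
  for (i in 1:10) {
    lo <- sample(seq(4355, 4500, by = 5), 1)
    hi <- sample(seq(lo, 4560, by = 5), 1)
    got <- nrow(genes_in_locus_range(sprintf("vnz_%05d", lo),
                                     sprintf("vnz_%05d", hi), ann))
    expect_equal(got, (hi - lo) / 5 + 1)
  }
})

test_that("config files mirror pipeline_config fields", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("# thresholds", "deg_fc_min: 2.0", "motif_fe_min: 1.9",
               "promoter_upstream: 300"), f)
  cfg <- read_config(f)
  expect_equal(cfg$deg_fc_min, 2.0)
  expect_equal(cfg$motif_fe_min, 1.9)
  expect_equal(cfg$promoter_upstream, 300L)
  expect_equal(cfg$deg_fdr_max, 0.05)  # untouched default

  writeLines('{"deg_fc_min": 1.75, "rng_seed": 5}', f)
  expect_equal(read_config(f)$deg_fc_min, 1.75)

  writeLines("no_such_key: 1", f)
  expect_error(read_config(f), "unknown")
  expect_error(pipeline_config(deg_fc_min = -1), "> 0")
})
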