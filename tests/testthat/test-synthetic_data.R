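test_that("generate_genome hits its GC target and is deterministic", {
  g <- generate_genome(1, 1e5, gc = 0.72)
  gc_obs <- mean(strsplit(g[[1]], "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc_obs - 0.72), 0.01)   # ~5 sigma binomial margin

  g2 <- generate_genome(1, 1e5, gc = 0.72)
  expect_identical(g, g2)

  g3 <- generate_genome(2, 1e5, gc = 0.5)
  expect_lt(abs(mean(strsplit(g3[[1]], "")[[1]] %in% c("G", "C")) - 0.5),
            0.01)
  expect_error(generate_genome(1, 1e5, gc = 1.2), "gc")
  expect_error(generate_genome(1, 100), "1e4|10000|>=")
})

test_that("generate_annotation makes step-5 tags and records operon truth", {
  cfg <- pipeline_config()
  ann <- generate_annotation(1, 200, genome_len = 400000L, cfg = cfg)
  expect_equal(ann$locus_tag, sprintf("syn_%05d", 5 * 1:200))
  expect_false(anyDuplicated(ann$locus_tag) > 0)

  # operon_frac 0 -> no operons inferred
  ann0 <- generate_annotation(2, 100, operon_frac = 0,
                              genome_len = 300000L, cfg = cfg)
  expect_length(infer_operons(ann0, cfg), 0)

  # the inference recovers the generator's own truth exactly
  ann5 <- generate_annotation(7, 200, operon_frac = 0.5,
                              genome_len = 400000L, cfg = cfg)
  truth <- attr(ann5, "operon_truth")
  got <- infer_operons(ann5, cfg)
  canon <- function(x) sort(vapply(x, paste, character(1), collapse = ","))
  expect_equal(canon(got), canon(truth))
  expect_gt(length(truth), 0)

  expect_error(generate_annotation(1, 500, genome_len = 100000L),
               "too large")
})

test_that("plant_motifs writes sites where it says it does", {
  cfg <- pipeline_config()
  genome <- generate_genome(3, 5e4)
  ann <- generate_annotation(3, 30, genome_len = 5e4, cfg = cfg)
  # one-hot PWM plants its consensus verbatim
  consensus <- "TTGACAATTGTCAACC"
  one_hot <- build_pwm(rep(consensus, 2), pseudocount = 0)
  targets <- ann$locus_tag[c(2, 10, 20)]
  out <- plant_motifs(genome, ann, one_hot, targets, seed = 4, cfg = cfg)
  ps <- out$truth$planted_sites
  expect_equal(nrow(ps), 3L)
  for (i in seq_len(nrow(ps))) {
    written <- substr(out$genome[[ps$chrom[i]]], ps$start[i] + 1, ps$end[i])
    want <- if (ps$strand[i] == "+") consensus else revcomp(consensus)
    expect_equal(written, want)
    expect_equal(ps$site[i], consensus)
  }
  # zero targets leaves the genome untouched
  out0 <- plant_motifs(genome, ann, one_hot, character(0), seed = 4,
                       cfg = cfg)
  expect_identical(out0$genome, genome)
})

test_that("planted sites are recovered by scanning (string-lookup oracle)", {
  cfg <- pipeline_config()
  genome <- generate_genome(5, 3e5)
  ann <- generate_annotation(5, 150, genome_len = 3e5, cfg = cfg)
  x <- default_motif_pwm()
  set.seed(3)
  targets <- sort(sample(ann$locus_tag, 50))
  out <- plant_motifs(genome, ann, x, targets, seed = 3, cfg = cfg)
  ps <- out$truth$planted_sites
  # oracle: the written substring equals site (or its revcomp) at the
  # recorded position
  for (i in seq_len(nrow(ps))) {
    written <- substr(out$genome[[1]], ps$start[i] + 1, ps$end[i])
    want <- if (ps$strand[i] == "+") ps$site[i] else revcomp(ps$site[i])
    expect_equal(written, want)
  }
  hits <- scan_sequences(x, out$genome, p_max = 1e-4)
  found <- vapply(seq_len(nrow(ps)), function(i)
    any(hits$start == ps$start[i]), logical(1))
  expect_gte(sum(found), 45)
})

test_that("simulate_peaks covers planted sites and is deterministic", {
  cfg <- pipeline_config()
  genome <- generate_genome(6, 1e5)
  ann <- generate_annotation(6, 40, genome_len = 1e5, cfg = cfg)
  x <- default_motif_pwm()
  out <- plant_motifs(genome, ann, x, ann$locus_tag[seq(1, 40, 4)],
                      seed = 6, cfg = cfg)
  gl <- stats::setNames(nchar(out$genome), names(out$genome))
  pk <- simulate_peaks(out$truth, n_noise = 0, seed = 8, genome_len = gl,
                       cfg = cfg)
  expect_equal(nrow(pk), 10L)
  frags <- prep_peaks(pk, cfg, gl)
  ps <- out$truth$planted_sites
  # each summit-centred 201-bp trim contains its planted site
  for (i in seq_len(nrow(ps))) {
    containing <- frags$start <= ps$start[i] & frags$end >= ps$end[i]
    expect_true(any(containing))
  }
  pk2 <- simulate_peaks(out$truth, n_noise = 0, seed = 8, genome_len = gl,
                        cfg = cfg)
  expect_identical(pk, pk2)

  # noise drawn entirely below the FE filter is removed by prep_peaks
  expect_warning(
    pk3 <- simulate_peaks(out$truth, n_noise = 50, fe_range = c(0.8, 1.749),
                          seed = 9, genome_len = gl, cfg = cfg),
    "straddle")
  kept <- prep_peaks(pk3, cfg, gl)
  expect_true(all(grepl("^signal_", kept$name)))
})

test_that("simulate_counts has the promised NB structure", {
  ann <- mk_annotation(1:1 * 1000, 500, "+")
  # single gene, log2FC 5: group mean ratio within 2x of 32
  set.seed(2)
  ratios <- replicate(40, {
    sim <- simulate_counts(ann, c(tst_00005 = 5), n_reps = 3,
                           dispersion = 0.05, seed = sample.int(1e6, 1))
    mean(sim$counts[1, 4:6]) / mean(sim$counts[1, 1:3])
  })
  expect_true(mean(ratios > 16 & ratios < 64) > 0.9)

  sim1 <- simulate_counts(ann, c(tst_00005 = 1), seed = 3)
  sim2 <- simulate_counts(ann, c(tst_00005 = 1), seed = 3)
  expect_identical(sim1$counts, sim2$counts)
  expect_error(simulate_counts(ann, numeric(0), n_reps = 1), "n_reps")
  expect_error(simulate_counts(ann, numeric(0), dispersion = 0), "dispersion")
  expect_error(simulate_counts(ann, numeric(0), lib_sizes = c(1, -1, 1, 1, 1, 1)),
               "positive")
})

test_that("write_dataset emits readable standard formats", {
  ds <- simulate_dataset(seed = 2, n_genes = 30, n_targets = 5,
                         n_indirect = 2, n_noise_peaks = 5)
  dir <- withr::local_tempdir()
  paths <- write_dataset(ds, dir)
  expect_identical(read_fasta(paths["fasta"]),
                   stats::setNames(ds$genome, names(ds$genome)))
  back_ann <- read_gff3(paths["gff3"])
  expect_equal(back_ann$locus_tag, ds$annotation$locus_tag)
  expect_equal(back_ann$start, ds$annotation$start)
  back_pk <- read_narrowpeak(paths["narrowpeak"])
  expect_equal(back_pk$summit, ds$peaks$summit)
  expect_equal(unname(as.matrix(read_counts(paths["counts"]))),
               unname(ds$counts))
  truth <- jsonlite::fromJSON(paths["truth"])
  expect_setequal(truth$direct_targets, ds$truth$direct_targets)
})
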