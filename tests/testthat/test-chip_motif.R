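test_that("prep_peaks trims to 201 bp, filters on FE inclusively, clips", {
  cfg <- pipeline_config()
  pk <- data.frame(chrom = "chr1",
                   start = c(500L, 500L, 500L, 0L),
                   end = c(1500L, 1500L, 1500L, 300L),
                   name = paste0("p", 1:4),
                   summit = c(800L, 900L, 1000L, 40L),
                   fold_enrichment = c(2.0, 1.74, 1.75, 3.0),
                   neg_log10_q = 5)
  out <- prep_peaks(pk, cfg, chrom_len = 1e5L)
  expect_equal(out$name, c("p1", "p3", "p4"))   # FE 1.74 dropped, 1.75 kept
  expect_equal(c(out$start[1], out$end[1]), c(700L, 901L))
  expect_equal(out$end[1] - out$start[1], 201L)
  # summit at 40 -> clipped to [0, 141)
  expect_equal(c(out$start[3], out$end[3]), c(0L, 141L))
  expect_error(prep_peaks(pk, cfg, chrom_len = 900L), "beyond")
})

test_that("shared_regions uses the 50-nt inclusive overlap rule", {
  cfg <- pipeline_config()
  a <- data.frame(chrom = "chr1", start = 0L, end = 201L)
  b50 <- data.frame(chrom = "chr1", start = 151L, end = 352L)
  b49 <- data.frame(chrom = "chr1", start = 152L, end = 353L)
  expect_equal(shared_regions(a, b50, cfg)$fraction, 1)
  expect_equal(shared_regions(a, b49, cfg)$fraction, 0)
  many <- data.frame(chrom = "chr1", start = c(0L, 500L), end = c(201L, 701L))
  expect_equal(shared_regions(many, many, cfg)$fraction, 1)
  expect_error(shared_regions(many[0, ], many, cfg), "empty")
})

test_that("build_pwm counts, applies pseudocounts, recovers a sampled PWM", {
  p <- build_pwm(rep("ACG", 4), pseudocount = 0)
  expect_equal(p$probs[, 1], c(A = 1, C = 0, G = 0, T = 0))
  expect_equal(p$probs[, 3], c(A = 0, C = 0, G = 1, T = 0))

  p2 <- build_pwm(c("AA", "AC"), pseudocount = 0)
  expect_equal(p2$probs[, 2], c(A = 0.5, C = 0.5, G = 0, T = 0))

  expect_error(build_pwm(c("AA", "ACA")), "equal")
  expect_error(build_pwm(c("AA", "AX")), "A/C/G/T")

  # multinomial recovery: 200 sites sampled from the default motif
  set.seed(21)
  truth <- default_motif_pwm()
  sites <- replicate(200, paste(vapply(seq_len(truth$width), function(j)
    sample(c("A", "C", "G", "T"), 1, prob = truth$probs[, j]),
    character(1)), collapse = ""))
  est <- build_pwm(sites, pseudocount = 1,
                   background = unname(truth$background))
  expect_lt(max(abs(est$probs - truth$probs)), 0.1)
})

test_that("iupac_consensus follows the column rules", {
  one_hot <- pwm(matrix(c(0, 0, 1, 0), 4, 1))
  expect_equal(iupac_consensus(one_hot), "G")
  r_col <- pwm(matrix(c(0.45, 0.05, 0.45, 0.05), 4, 1))
  expect_equal(iupac_consensus(r_col), "R")
  uniform <- pwm(matrix(0.25, 4, 1))
  expect_equal(iupac_consensus(uniform), "N")
  # the default planted motif prints its designed consensus
  expect_equal(iupac_consensus(default_motif_pwm()), "TGGCCGRAWHYSRHC")
})

test_that("pwm_pvalue_table matches exhaustive enumeration for short PWMs", {
  # width-1 single-base null
  p1 <- pwm(matrix(c(0.97, 0.01, 0.01, 0.01), 4, 1))
  tab1 <- pwm_pvalue_table(p1)
  max_score <- log2(0.97 / 0.25)
  expect_equal(pwm_pvalue(tab1, max_score), 0.25)

  set.seed(5)
  for (w in c(2, 3, 5)) {
    probs <- matrix(stats::rgamma(4 * w, 1) + 0.05, 4, w)
    probs <- sweep(probs, 2, colSums(probs), `/`)
    bg <- c(0.2, 0.3, 0.3, 0.2)
    x <- pwm(probs, background = bg)
    tab <- pwm_pvalue_table(x, granularity = 1e-3)
    oracle <- enumerate_pvalues(x)
    # DP tail equals the enumerated tail exactly on the shared integer grid
    expect_equal(pwm_pvalue(tab, oracle$iscore, integer_score = TRUE),
                 oracle$ipval, tolerance = 1e-9)
    # discretization moves each word's score by at most half a bin per
    # column, so grid p-values bracket the exact ones within one bin
    expect_lt(max(abs(oracle$iscore * 1e-3 - oracle$score)), w * 5e-4 + 1e-9)
    # survival function is non-increasing in score
    expect_true(all(diff(tab$surv) <= 1e-15))
  }
})

test_that("scan_sequences finds planted words on both strands", {
  consensus <- "TGGCA"
  x <- build_pwm(rep(consensus, 4), pseudocount = 0.4)
  bgseq <- paste(rep("C", 60), collapse = "")
  seq_fwd <- paste0(substr(bgseq, 1, 20), consensus, substr(bgseq, 1, 20))
  hits <- scan_sequences(x, c(s = seq_fwd), p_max = 1e-2)
  expect_true(any(hits$start == 20 & hits$strand == "+"))
  expect_equal(hits$matched_seq[hits$start == 20 & hits$strand == "+"],
               consensus)

  seq_rev <- paste0(substr(bgseq, 1, 20), revcomp(consensus),
                    substr(bgseq, 1, 20))
  hits_rev <- scan_sequences(x, c(s = seq_rev), p_max = 1e-2)
  expect_true(any(hits_rev$start == 20 & hits_rev$strand == "-"))

  # threshold below best attainable p -> no hits
  tab <- pwm_pvalue_table(x)
  best_p <- min(tab$surv)
  expect_equal(nrow(scan_sequences(x, c(s = seq_fwd),
                                   p_max = best_p / 2, strict = TRUE)), 0L)
  expect_error(scan_sequences(x, c(s = seq_fwd), p_max = 0), "p_max")
})

test_that("scanning a sequence and its reverse complement mirrors hits", {
  set.seed(9)
  x <- default_motif_pwm()
  seq <- generate_genome(4, 1e4, gc = 0.6)[[1]]
  h_fwd <- scan_sequences(x, c(s = seq), p_max = 1e-3)
  h_rc <- scan_sequences(x, c(s = revcomp(seq)), p_max = 1e-3)
  L <- nchar(seq)
  # map rc hits back to forward coordinates with strands swapped
  mapped <- data.frame(start = L - h_rc$end,
                       strand = ifelse(h_rc$strand == "+", "-", "+"))
  key <- function(d) sort(paste(d$start, d$strand))
  expect_equal(key(mapped), key(h_fwd))
})

test_that("scan equals the brute-force oracle for width <= 5", {
  set.seed(13)
  probs <- matrix(stats::rgamma(12, 1) + 0.05, 4, 3)
  probs <- sweep(probs, 2, colSums(probs), `/`)
  x <- pwm(probs, background = rep(0.25, 4))
  seq <- generate_genome(8, 2e4, gc = 0.5)[[1]]
  oracle <- enumerate_pvalues(x)
  for (strict in c(TRUE, FALSE)) {
    p_max <- 0.02
    hits <- scan_sequences(x, c(s = seq), p_max = p_max,
                           both_strands = FALSE, strict = strict)
    # oracle: exact p of every window via word lookup (expand.grid order:
    # first base fastest)
    e <- match(strsplit(seq, "")[[1]], c("A", "C", "G", "T"))
    idx <- e[1:(nchar(seq) - 2)] + (e[2:(nchar(seq) - 1)] - 1) * 4 +
      (e[3:nchar(seq)] - 1) * 16
    pv <- oracle$pval[idx]
    want <- if (strict) which(pv < p_max) else which(pv <= p_max)
    expect_equal(hits$start, want - 1L)
  }
})

test_that("motifs round-trip through MEME minimal format", {
  x <- default_motif_pwm()
  f <- withr::local_tempfile(fileext = ".meme")
  write_meme(x, f, name = "planted")
  back <- read_meme(f)
  expect_equal(back$width, x$width)
  expect_lt(max(abs(back$probs - x$probs)), 1e-5)
  expect_equal(unname(back$background), unname(x$background),
               tolerance = 1e-5)
})
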