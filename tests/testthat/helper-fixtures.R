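# Shared fixtures and independent oracles. All fixtures are built in code.

# small annotation builder: genes at given starts/lengths on one chromosome
mk_annotation <- function(starts, lens, strands, prefix = "tst",
                          chrom = "chr1") {
  n <- length(starts)
  df <- data.frame(
    locus_tag = sprintf("%s_%05d", prefix, 5L * seq_len(n)),
    chrom = chrom, start = as.integer(starts),
    end = as.integer(starts + lens), strand = strands,
    product = "", stringsAsFactors = FALSE)
  class(df) <- c("gene_annotation", "data.frame")
  df
}

# step-5 annotation mirroring a locus-tag range (for cluster gene counting)
mk_step5_annotation <- function(prefix, first_suffix, last_suffix) {
  suf <- seq(first_suffix, last_suffix, by = 5L)
  df <- data.frame(
    locus_tag = sprintf("%s_%05d", prefix, suf),
    chrom = "chr1", start = seq_along(suf) * 1000L,
    end = seq_along(suf) * 1000L + 800L, strand = "+",
    product = "", stringsAsFactors = FALSE)
  class(df) <- c("gene_annotation", "data.frame")
  df
}

# brute-force BH step-up, straight from the definition
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# brute-force enumeration oracle over all 4^w words (widths <= 5 only):
# exact continuous scores/probabilities/p-values, plus the same quantities
# on the DP's integer grid for exact cross-checks
enumerate_pvalues <- function(x, granularity = 1e-3) {
  w <- x$width
  words <- expand.grid(rep(list(1:4), w))
  score <- numeric(nrow(words))
  iscore <- numeric(nrow(words))
  prob <- numeric(nrow(words))
  smat <- log2(x$probs / x$background)
  imat <- round(smat / granularity)
  for (i in seq_len(nrow(words))) {
    idx <- as.integer(words[i, ])
    score[i] <- sum(smat[cbind(idx, seq_len(w))])
    iscore[i] <- sum(imat[cbind(idx, seq_len(w))])
    prob[i] <- prod(x$background[idx])
  }
  list(words = words, score = score, iscore = iscore, prob = prob,
       pval = vapply(score, function(s) sum(prob[score >= s - 1e-12]),
                     numeric(1)),
       ipval = vapply(iscore, function(s) sum(prob[iscore >= s]),
                      numeric(1)))
}

# memoized heavy end-to-end world shared by acceptance tests
.world_cache <- new.env(parent = emptyenv())
acceptance_world <- function() {
  if (is.null(.world_cache$world)) {
    ds <- simulate_dataset(seed = 11)
    res <- infer_regulon(ds$genome, ds$annotation, ds$peaks, ds$counts,
                         ds$groups, ds$cfg, restarts = 8L, seed = 1L,
                         relaxed = TRUE)
    .world_cache$world <- list(ds = ds, res = res)
  }
  .world_cache$world
}

# printed cluster table (id, type, range) used for locus-range arithmetic
bgc_printed_ranges <- function() {
  data.frame(
    bgc_id = 1:32,
    bgc_type = "SM",
    first_tag = sprintf("vnz_%05d", c(
      1060, 1250, 2200, 2580, 2920, 3615, 4355, 9090, 12535, 15295,
      20080, 20635, 22965, 25145, 25310, 26470, 26765, 27055, 28840,
      29390, 30285, 30505, 31755, 31920, 32195, 33355, 33695, 34675,
      34995, 35165, 35605, 36585)),
    last_tag = sprintf("vnz_%05d", c(
      1105, 1320, 2530, 2675, 2995, 3695, 4560, 9185, 12650, 15400,
      20290, 20675, 23015, 25260, 25435, 26620, 26890, 27160, 28880,
      29720, 30395, 30990, 31865, 32015, 32230, 33670, 33730, 34880,
      35080, 35215, 35770, 36745)),
    stringsAsFactors = FALSE)
}
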