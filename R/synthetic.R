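#' Simulate a high-GC bacterial genome
#'
#' I.i.d. bases with P(G) = P(C) = gc/2 (strand-symmetric), emulating a
#' Streptomyces-like ~72% GC background.
#'
#' @param seed RNG seed; the sequence is a pure function of seed, length
#'   and gc.
#' @param length genome length (>= 1e4).
#' @param gc GC fraction in (0, 1).
#' @param chrom chromosome name.
#' @return named character vector of length 1.
#' @export
generate_genome <- function(seed, length, gc = 0.72, chrom = "chr1") {
  if (length < 1e4) stop("genome length must be >= 1e4")
  if (gc <= 0 || gc >= 1) stop("gc must be in (0, 1)")
  set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seq <- paste(sample(DNA_BASES, length, replace = TRUE, prob = p),
               collapse = "")
  stats::setNames(seq, chrom)
}

#' Simulate a gene annotation with step-5 locus tags
#'
#' Lays genes along a single chromosome in blocks: with the appropriate
#' probability a block is a 2-4 gene operon-like run (intra-block gaps well
#' below `cfg$operon_max_gap`) so that roughly `operon_frac` of genes end
#' up inside operons; otherwise a singleton. Blocks alternate strand and
#' are separated by 400-600 bp so every promoter window is well-defined.
#' Locus tags are "syn_" plus suffixes in steps of 5. The generator records
#' its own operon truth in the `operon_truth` attribute.
#'
#' @param seed RNG seed.
#' @param n_genes number of genes.
#' @param mean_len mean gene length in bp (sd = mean/5, floor 300).
#' @param operon_frac target fraction of genes inside operons.
#' @param genome_len chromosome length the genes must fit in.
#' @param chrom chromosome name.
#' @param cfg a [pipeline_config()].
#' @return a `gene_annotation` with attribute `operon_truth` (list of locus
#'   tag vectors, coding-strand order, as [infer_operons()] reports them).
#' @export
generate_annotation <- function(seed, n_genes, mean_len = 900,
                                operon_frac = 0.3, genome_len,
                                chrom = "chr1", cfg = pipeline_config()) {
  if (operon_frac < 0 || operon_frac >= 1) stop("operon_frac must be in [0, 1)")
  set.seed(seed)
  mean_run <- 3
  p_operon <- if (operon_frac == 0) 0 else {
    operon_frac / (mean_run * (1 - operon_frac) + operon_frac)
  }
  pos <- 400L
  strand <- "+"
  starts <- ends <- integer(n_genes)
  strands <- character(n_genes)
  blocks <- list()
  i <- 0L
  while (i < n_genes) {
    k <- if (stats::runif(1) < p_operon) sample(2:4, 1) else 1L
    k <- min(k, n_genes - i)
    block_idx <- integer(0)
    for (g in seq_len(k)) {
      len <- max(300L, round_half_up(stats::rnorm(1, mean_len, mean_len / 5)))
      i <- i + 1L
      starts[i] <- pos
      ends[i] <- pos + len
      strands[i] <- strand
      block_idx <- c(block_idx, i)
      pos <- ends[i] + if (g < k) sample(5:45, 1) else sample(400:600, 1)
    }
    if (length(block_idx) >= 2) blocks[[length(blocks) + 1L]] <- block_idx
    strand <- if (strand == "+") "-" else "+"
  }
  if (max(ends) + 400L > genome_len) {
    stop("n_genes too large for genome length ", genome_len,
         " (need >= ", max(ends) + 400L, ")")
  }
  tags <- sprintf("syn_%05d", 5L * seq_len(n_genes))
  ann <- gene_annotation(data.frame(
    locus_tag = tags, chrom = chrom, start = starts, end = ends,
    strand = strands, product = "hypothetical protein",
    stringsAsFactors = FALSE))
  truth <- lapply(blocks, function(idx) {
    t <- tags[idx]
    if (strands[idx[1]] == "-") t <- rev(t)
    structure(t, strand = strands[idx[1]])
  })
  attr(ann, "operon_truth") <- truth
  ann
}

#' The default planted binding motif
#'
#' A 15-bp PWM whose IUPAC consensus is TGGCCGRAWHYSRHC: a strongly
#' conserved 10-bp core followed by a degenerate 5-bp 3' extension, the
#' shape of the AdpA-family binding site. Fixed positions carry probability
#' 0.94; two-fold degenerate positions split 0.47/0.47; the three-fold
#' position splits 0.32 three ways. Background is 72% GC, strand-symmetric.
#'
#' @return a [pwm()].
#' @export
default_motif_pwm <- function() {
  bg <- c(A = 0.14, C = 0.36, G = 0.36, T = 0.14)
  col <- function(...) {
    p <- c(...)
    stats::setNames(p / sum(p), DNA_BASES)
  }
  fixed <- function(b) {
    p <- rep(0.02, 4)
    p[match(b, DNA_BASES)] <- 0.94
    p
  }
  two <- function(b1, b2) {
    p <- rep(0.03, 4)
    p[match(c(b1, b2), DNA_BASES)] <- 0.47
    p
  }
  three <- function(b1, b2, b3) {
    p <- rep(0.04, 4)
    p[match(c(b1, b2, b3), DNA_BASES)] <- 0.32
    p
  }
  probs <- cbind(
    fixed("T"), fixed("G"), fixed("G"), fixed("C"), fixed("C"),
    fixed("G"), two("A", "G"), fixed("A"), two("A", "T"),
    three("A", "C", "T"),                       # end of the 10-bp core
    two("C", "T"), two("C", "G"), two("A", "G"),
    three("A", "C", "T"), fixed("C")            # 5-bp 3' extension
  )
  pwm(probs, background = bg, n_sites = 200L)
}

#' Plant motif instances in promoter windows
#'
#' For each target gene, one site sampled column-by-column from the PWM is
#' written at a uniform-random offset inside the gene's promoter window, on
#' a uniform-random strand (minus-strand sites are written as their reverse
#' complement). Sites are kept non-overlapping by resampling the offset
#' (capped retries). Positions and sampled sequences are recorded in the
#' returned truth.
#'
#' @param genome named character vector (single chromosome per gene's
#'   chrom).
#' @param annotation a `gene_annotation`.
#' @param x the [pwm()] to plant.
#' @param targets locus tags to receive one site each.
#' @param seed RNG seed.
#' @param cfg a [pipeline_config()] (for the promoter window).
#' @return list with `genome` (modified) and `truth`: a `synthetic_truth`
#'   list holding planted_pwm, planted_sites (locus_tag, chrom, start, end,
#'   strand, site), direct_targets.
#' @export
plant_motifs <- function(genome, annotation, x, targets, seed,
                         cfg = pipeline_config()) {
  if (!all(targets %in% annotation$locus_tag)) {
    stop("target(s) absent from annotation: ",
         paste(setdiff(targets, annotation$locus_tag), collapse = ", "))
  }
  set.seed(seed)
  chrom_len <- stats::setNames(nchar(genome), names(genome))
  windows <- promoter_window(annotation, cfg, chrom_len)
  w <- x$width
  sites <- list()
  occupied <- data.frame(start = integer(), end = integer(),
                         chrom = character())
  chars <- strsplit(genome, "")
  for (tag in targets) {
    win <- windows[windows$locus_tag == tag, ]
    max_off <- (win$end - win$start) - w
    if (max_off < 0) stop("promoter window too small for gene ", tag)
    placed <- FALSE
    for (try in 1:50) {
      off <- sample.int(max_off + 1L, 1L) - 1L
      s0 <- win$start + off
      clash <- any(occupied$chrom == win$chrom &
                     occupied$start < s0 + w & occupied$end > s0)
      if (!clash) { placed <- TRUE; break }
    }
    if (!placed) stop("could not place a non-overlapping site for ", tag)
    strand <- sample(c("+", "-"), 1L)
    site <- paste(vapply(seq_len(w), function(j) {
      sample(DNA_BASES, 1L, prob = x$probs[, j])
    }, character(1)), collapse = "")
    written <- if (strand == "+") site else revcomp(site)
    chars[[win$chrom]][(s0 + 1L):(s0 + w)] <-
      strsplit(written, "")[[1]]
    occupied <- rbind(occupied, data.frame(start = s0, end = s0 + w,
                                           chrom = win$chrom))
    sites[[length(sites) + 1L]] <- data.frame(
      locus_tag = tag, chrom = win$chrom, start = s0, end = s0 + w,
      strand = strand, site = site, stringsAsFactors = FALSE)
  }
  genome_out <- vapply(chars, paste, character(1), collapse = "")
  truth <- structure(list(
    planted_pwm = x,
    planted_sites = if (length(sites) > 0) do.call(rbind, sites) else
      data.frame(locus_tag = character(), chrom = character(),
                 start = integer(), end = integer(), strand = character(),
                 site = character()),
    direct_targets = targets,
    deg_truth = NULL, peak_truth = NULL
  ), class = "synthetic_truth")
  list(genome = genome_out, truth = truth)
}

#' Simulate ChIP peaks over planted sites plus noise
#'
#' One peak per planted site (summit within +/- 20 bp of the site midpoint,
#' width ~ Normal(width_mean, width_mean/5) truncated at 200, fold
#' enrichment drawn above the motif filter) plus `n_noise` peaks at
#' motif-free positions with fold enrichments spanning the filter boundary
#' (uniform over `fe_range`, which must straddle `cfg$motif_fe_min`).
#' Placement collisions with planted sites are resolved by resampling
#' (capped).
#'
#' @param truth a `synthetic_truth` from [plant_motifs()].
#' @param n_noise number of noise peaks.
#' @param width_mean mean peak width (default 1050 bp, the observed scale
#'   of bound regions).
#' @param fe_range noise fold-enrichment range (min < filter < max).
#' @param seed RNG seed.
#' @param genome_len chromosome length(s), named.
#' @param cfg a [pipeline_config()].
#' @return peaks data.frame with a `signal` logical column recorded in
#'   `truth$peak_truth` form (peak name -> locus_tag or NA).
#' @export
simulate_peaks <- function(truth, n_noise, width_mean = 1050,
                           fe_range = c(0.8, 5), seed, genome_len,
                           cfg = pipeline_config()) {
  if (!(fe_range[1] < cfg$motif_fe_min && cfg$motif_fe_min < fe_range[2])) {
    warning("fe_range does not straddle motif_fe_min; ",
            "the enrichment filter will not be exercised")
  }
  set.seed(seed)
  ps <- truth$planted_sites
  rows <- list()
  mk_peak <- function(chrom, summit, fe, name, len) {
    width <- max(200L, round_half_up(stats::rnorm(1, width_mean,
                                                  width_mean / 5)))
    start <- max(0L, summit - width %/% 2L)
    end <- min(len, start + width)
    if (summit < start || summit >= end) {
      start <- max(0L, summit - 100L)
      end <- min(len, summit + 100L)
    }
    data.frame(chrom = chrom, start = start, end = end, name = name,
               summit = summit, fold_enrichment = fe,
               neg_log10_q = stats::runif(1, 2, 40),
               stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(ps))) {
    len <- genome_len[[ps$chrom[i]]]
    summit <- (ps$start[i] + ps$end[i]) %/% 2L + sample(-20:20, 1L)
    summit <- min(max(summit, 0L), len - 1L)
    fe <- stats::runif(1, cfg$motif_fe_min + 0.25,
                       max(fe_range[2], cfg$motif_fe_min + 1.25))
    rows[[length(rows) + 1L]] <-
      cbind(mk_peak(ps$chrom[i], summit, fe, sprintf("signal_%04d", i), len),
            source_tag = ps$locus_tag[i])
  }
  chroms <- names(genome_len)
  for (i in seq_len(n_noise)) {
    ch <- if (length(chroms) == 1) chroms else sample(chroms, 1)
    len <- genome_len[[ch]]
    ok <- FALSE
    for (try in 1:1000) {
      summit <- sample.int(len - 400L, 1L) + 200L
      near <- any(ps$chrom == ch &
                    abs((ps$start + ps$end) / 2 - summit) < 300)
      if (!near) { ok <- TRUE; break }
    }
    if (!ok) stop("could not place noise peak away from planted sites")
    fe <- stats::runif(1, fe_range[1], fe_range[2])
    rows[[length(rows) + 1L]] <-
      cbind(mk_peak(ch, summit, fe, sprintf("noise_%04d", i), len),
            source_tag = NA_character_)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  pk <- peaks(out)
  pk$source_tag <- out$source_tag
  pk
}

#' Simulate negative-binomial RNA-seq counts for two conditions
#'
#' counts ~ NB(mean = baseline * lib * 2^(log2fc * mutant), variance =
#' mu + dispersion * mu^2); baselines are log-uniform over [50, 5000].
#' The first `n_reps` columns are the reference condition (complemented
#' strain), the rest the deletion mutant, mirroring a two-group design with
#' three biological replicates.
#'
#' @param annotation a `gene_annotation` (row order = matrix row order).
#' @param deg_truth named numeric vector of true log2 fold changes
#'   (mutant vs reference); genes missing from it are treated as 0.
#' @param n_reps replicates per group (>= 2).
#' @param dispersion NB dispersion alpha (> 0).
#' @param lib_sizes relative library-size factors, length 2 * n_reps
#'   (default all 1).
#' @param seed RNG seed.
#' @return list with `counts` (genes x samples integer matrix) and
#'   `groups` (factor, reference level first).
#' @export
simulate_counts <- function(annotation, deg_truth, n_reps = 3,
                            dispersion = 0.05, lib_sizes = NULL, seed = 1L) {
  if (n_reps < 2) stop("n_reps must be >= 2")
  if (dispersion <= 0) stop("dispersion must be > 0")
  n_samples <- 2L * n_reps
  if (is.null(lib_sizes)) lib_sizes <- rep(1, n_samples)
  if (length(lib_sizes) != n_samples || any(lib_sizes <= 0)) {
    stop("lib_sizes must be ", n_samples, " positive factors")
  }
  set.seed(seed)
  n <- nrow(annotation)
  lfc <- stats::setNames(rep(0, n), annotation$locus_tag)
  known <- intersect(names(deg_truth), names(lfc))
  lfc[known] <- deg_truth[known]
  baseline <- 10^stats::runif(n, log10(50), log10(5000))
  is_mut <- rep(c(0, 1), each = n_reps)
  mu <- outer(baseline, lib_sizes) * 2^outer(lfc, is_mut)
  counts <- matrix(stats::rnbinom(length(mu), size = 1 / dispersion,
                                  mu = mu), n, n_samples)
  rownames(counts) <- annotation$locus_tag
  colnames(counts) <- c(paste0("comp_", seq_len(n_reps)),
                        paste0("mut_", seq_len(n_reps)))
  groups <- factor(rep(c("complemented", "mutant"), each = n_reps),
                   levels = c("complemented", "mutant"))
  list(counts = counts, groups = groups)
}

#' Simulate a complete ground-truthed dataset
#'
#' Orchestrates the generators into one coherent world: a high-GC genome,
#' a step-5 annotation with operons, a planted binding motif in the
#' promoters of randomly chosen direct-target genes (operon leaders or
#' singletons, where bacterial promoters live), ChIP peaks over the planted
#' sites plus noise peaks, and NB counts in which direct targets and a
#' smaller set of indirect genes carry |log2FC| uniform in [1, 3] with
#' random sign. All randomness derives from `seed`.
#'
#' @param seed master seed (sub-generators use seed, seed+1, ...).
#' @param n_genes,n_targets,n_indirect,n_noise_peaks world size.
#' @param gc GC fraction.
#' @param mean_gene_len mean gene length.
#' @param operon_frac fraction of genes in operons.
#' @param dispersion NB dispersion.
#' @param n_reps replicates per condition.
#' @param cfg a [pipeline_config()].
#' @return list: genome, annotation, operons (truth), truth
#'   (`synthetic_truth` with deg_truth and peak_truth filled), peaks,
#'   counts, groups, chrom_len.
#' @export
simulate_dataset <- function(seed = 11L, n_genes = 200L, n_targets = 50L,
                             n_indirect = 20L, n_noise_peaks = 100L,
                             gc = 0.72, mean_gene_len = 900L,
                             operon_frac = 0.3, dispersion = 0.05,
                             n_reps = 3L, cfg = pipeline_config()) {
  genome_len <- as.integer(n_genes * (mean_gene_len + 650) + 2000)
  genome <- generate_genome(seed, genome_len, gc)
  ann <- generate_annotation(seed + 1L, n_genes, mean_gene_len,
                             operon_frac, genome_len, cfg = cfg)
  operons <- attr(ann, "operon_truth")
  downstream <- unlist(lapply(operons, function(o) o[-1]))
  eligible <- setdiff(ann$locus_tag, downstream)
  if (length(eligible) < n_targets) stop("not enough promoter-leading genes")
  set.seed(seed + 2L)
  targets <- sort(sample(eligible, n_targets))
  planted <- plant_motifs(genome, ann, default_motif_pwm(), targets,
                          seed + 3L, cfg)
  truth <- planted$truth
  set.seed(seed + 4L)
  effect <- function(n) {
    stats::runif(n, 1, 3) * sample(c(-1, 1), n, replace = TRUE)
  }
  deg_truth <- stats::setNames(effect(n_targets), targets)
  pool <- setdiff(ann$locus_tag, targets)
  indirect <- sort(sample(pool, min(n_indirect, length(pool))))
  deg_truth <- c(deg_truth, stats::setNames(effect(length(indirect)),
                                            indirect))
  truth$deg_truth <- deg_truth
  chrom_len <- stats::setNames(nchar(planted$genome), names(planted$genome))
  pk <- simulate_peaks(truth, n_noise_peaks, seed = seed + 5L,
                       genome_len = chrom_len, cfg = cfg)
  truth$peak_truth <- pk
  sim <- simulate_counts(ann, deg_truth, n_reps = n_reps,
                         dispersion = dispersion, seed = seed + 6L)
  list(genome = planted$genome, annotation = ann, operons = operons,
       truth = truth, peaks = pk, counts = sim$counts,
       groups = sim$groups, chrom_len = chrom_len, cfg = cfg)
}

#' Write a simulated dataset to disk in standard formats
#'
#' FASTA genome, GFF3 annotation, narrowPeak peaks, counts TSV, and a JSON
#' ground-truth file.
#'
#' @param ds result of [simulate_dataset()].
#' @param dir output directory.
#' @return invisible named vector of paths.
#' @export
write_dataset <- function(ds, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    fasta = file.path(dir, "genome.fa"),
    gff3 = file.path(dir, "annotation.gff3"),
    narrowpeak = file.path(dir, "peaks.narrowPeak"),
    counts = file.path(dir, "counts.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_fasta(ds$genome, paths["fasta"])
  write_gff3(ds$annotation, paths["gff3"])
  write_narrowpeak(ds$peaks, paths["narrowpeak"])
  write_counts(ds$counts, paths["counts"])
  jsonlite::write_json(list(
    direct_targets = ds$truth$direct_targets,
    planted_sites = ds$truth$planted_sites,
    deg_truth = as.list(ds$truth$deg_truth),
    planted_consensus = iupac_consensus(ds$truth$planted_pwm),
    operons = lapply(ds$operons, as.character)
  ), paths["truth"], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
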