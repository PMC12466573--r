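#' Scan sequences for PWM matches at an exact p-value threshold
#'
#' FIMO-style scan: every window of PWM width on the forward strand (and,
#' when `both_strands`, on the reverse complement, reported in the forward
#' frame) is scored in log-odds bits; windows whose exact tail p-value
#' passes the threshold become hits. The stringent mode of the published
#' workflow uses a strict inequality (p < p_max) while the relaxed
#' genome-wide mode uses p <= p_max; choose with `strict`.
#' Windows containing N are skipped.
#'
#' @param x a [pwm()].
#' @param sequences named character vector of A/C/G/T/N sequences.
#' @param p_max p-value threshold (> 0).
#' @param both_strands scan the minus strand too (default TRUE).
#' @param strict use strict `<` (stringent) rather than `<=` (relaxed).
#' @param table optional precomputed [pwm_pvalue_table()]; built on the fly
#'   otherwise.
#' @param granularity grid for the on-the-fly table.
#' @return data.frame of hits: chrom (sequence name), start, end (0-based
#'   half-open, forward frame), strand, score (bits), p_value, matched_seq
#'   (the motif-strand word).
#' @export
scan_sequences <- function(x, sequences, p_max, both_strands = TRUE,
                           strict = FALSE, table = NULL,
                           granularity = 1e-3) {
  if (p_max <= 0) stop("p_max must be > 0")
  if (is.null(names(sequences))) {
    names(sequences) <- paste0("seq", seq_along(sequences))
  }
  if (is.null(table)) table <- pwm_pvalue_table(x, granularity)
  g <- table$granularity
  ints <- pwm_int_scores(x, g)
  ints_rc <- ints[4:1, x$width:1, drop = FALSE]
  thr <- pwm_score_threshold(table, p_max, strict)
  res <- list()
  for (nm in names(sequences)) {
    seq <- toupper(sequences[[nm]])
    L <- nchar(seq)
    if (L < x$width) next
    e <- encode_dna(seq)
    n_win <- L - x$width + 1L
    mats <- list(`+` = ints, `-` = ints_rc)
    if (!both_strands) mats <- mats["+"]
    for (strand in names(mats)) {
      m <- mats[[strand]]
      s <- numeric(n_win)
      for (j in seq_len(x$width)) {
        s <- s + m[cbind(e[j:(n_win + j - 1L)], j)]
      }
      pass <- which(!is.na(s) & s >= thr)
      if (length(pass) == 0) next
      words <- substring(seq, pass, pass + x$width - 1L)
      if (strand == "-") words <- vapply(words, revcomp, character(1))
      res[[length(res) + 1L]] <- data.frame(
        chrom = nm, start = pass - 1L, end = pass - 1L + x$width,
        strand = strand, score = s[pass] * g,
        p_value = pwm_pvalue(table, s[pass], integer_score = TRUE),
        matched_seq = unname(words), stringsAsFactors = FALSE
      )
    }
  }
  if (length(res) == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      score = numeric(), p_value = numeric(),
                      matched_seq = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  out <- out[order(out$chrom, out$start, out$strand), ]
  rownames(out) <- NULL
  out
}

#' Scan genomic intervals and report hits in genome coordinates
#'
#' Extracts each interval's sequence from the genome, scans it with
#' [scan_sequences()], and lifts hit coordinates back to the chromosome
#' frame. Duplicate hits arising from overlapping intervals are collapsed.
#'
#' @param x a [pwm()].
#' @param genome named character vector of chromosome sequences.
#' @param intervals data.frame with chrom, start, end (0-based half-open).
#' @param ... passed to [scan_sequences()].
#' @return hit data.frame in genome coordinates.
#' @export
scan_intervals <- function(x, genome, intervals, ...) {
  seqs <- extract_sequences(genome, intervals)
  hits <- scan_sequences(x, seqs, ...)
  if (nrow(hits) == 0) return(hits)
  i <- as.integer(hits$chrom)
  hits$start <- hits$start + intervals$start[i]
  hits$end <- hits$end + intervals$start[i]
  hits$chrom <- intervals$chrom[i]
  hits <- unique(hits)
  hits <- hits[order(hits$chrom, hits$start, hits$strand), ]
  rownames(hits) <- NULL
  hits
}

#' Extract interval sequences from a genome
#'
#' @param genome named character vector of chromosome sequences.
#' @param intervals data.frame with chrom, start, end (0-based half-open).
#' @return character vector of sequences named by interval index.
#' @export
extract_sequences <- function(genome, intervals) {
  if (any(!intervals$chrom %in% names(genome))) {
    stop("interval chromosome(s) absent from genome")
  }
  len <- nchar(genome)[intervals$chrom]
  if (any(intervals$start < 0) || any(intervals$end > len)) {
    stop("interval outside chromosome")
  }
  out <- substring(genome[intervals$chrom], intervals$start + 1L,
                   intervals$end)
  names(out) <- as.character(seq_len(nrow(intervals)))
  out
}
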