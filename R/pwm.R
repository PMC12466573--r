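#' Position weight matrix constructor
#'
#' @param probs 4 x width matrix of per-position base probabilities, rows in
#'   A,C,G,T order; each column must sum to 1.
#' @param background length-4 base composition of the null model (sums to 1).
#' @param pseudocount pseudocount recorded with the model.
#' @param n_sites number of sites the matrix was estimated from.
#' @return object of class `pwm`.
#' @export
pwm <- function(probs, background = rep(0.25, 4), pseudocount = 0,
                n_sites = 0L) {
  probs <- as.matrix(probs)
  if (nrow(probs) != 4) stop("probs must have 4 rows (A,C,G,T)")
  if (any(abs(colSums(probs) - 1) > 1e-9)) stop("pwm columns must sum to 1")
  if (abs(sum(background) - 1) > 1e-9) stop("background must sum to 1")
  if (pseudocount > 0 && any(probs <= 0)) {
    stop("all probabilities must be > 0 when pseudocount > 0")
  }
  rownames(probs) <- DNA_BASES
  names(background) <- DNA_BASES
  structure(list(width = ncol(probs), probs = probs,
                 background = background, pseudocount = pseudocount,
                 n_sites = as.integer(n_sites)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm: width %d, %d sites, consensus %s\n",
              x$width, x$n_sites, iupac_consensus(x)))
  print(round(x$probs, 3))
  invisible(x)
}

#' Estimate a PWM from aligned sites
#'
#' probs[b, j] = (count(b, j) + pseudocount * background[b]) /
#' (n_sites + pseudocount).
#'
#' @param sites character vector of >= 2 equal-length A/C/G/T sequences.
#' @param pseudocount additive pseudocount, distributed by background.
#' @param background length-4 background composition (A,C,G,T).
#' @return a [pwm()].
#' @export
build_pwm <- function(sites, pseudocount = 0, background = rep(0.25, 4)) {
  if (length(sites) < 2) stop("need >= 2 sites")
  w <- unique(nchar(sites))
  if (length(w) != 1) stop("sites must have equal lengths")
  if (any(grepl("[^ACGT]", toupper(sites)))) stop("sites must be A/C/G/T only")
  mat <- vapply(toupper(sites), encode_dna, integer(w))
  counts <- matrix(0, 4, w)
  for (j in seq_len(w)) counts[, j] <- tabulate(mat[j, ], nbins = 4)
  probs <- (counts + pseudocount * background) / (length(sites) + pseudocount)
  pwm(probs, background = background, pseudocount = pseudocount,
      n_sites = length(sites))
}

# IUPAC ambiguity sets used for consensus calling, smallest first.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G")
)

#' IUPAC consensus of a PWM
#'
#' Per column: a single base is called when its probability is >= 0.5 and
#' the runner-up is < 0.25; otherwise the smallest IUPAC degeneracy set
#' whose members each have probability >= 0.25 and jointly exceed 0.75 is
#' called (ties resolved towards the higher joint probability); columns
#' matching no set are reported as N.
#'
#' @param x a [pwm()].
#' @return consensus string, one IUPAC code per column.
#' @export
iupac_consensus <- function(x) {
  codes <- vapply(seq_len(x$width), function(j) {
    p <- x$probs[, j]
    ord <- order(p, decreasing = TRUE)
    if (p[ord[1]] >= 0.5 && p[ord[2]] < 0.25) return(DNA_BASES[ord[1]])
    sizes <- vapply(IUPAC_SETS, length, integer(1))
    for (k in 2:3) {
      cand <- names(IUPAC_SETS)[sizes == k]
      ok <- vapply(cand, function(code) {
        members <- IUPAC_SETS[[code]]
        all(p[members] >= 0.25) && sum(p[members]) > 0.75
      }, logical(1))
      if (any(ok)) {
        tots <- vapply(cand[ok], function(code) sum(p[IUPAC_SETS[[code]]]),
                       numeric(1))
        return(cand[ok][which.max(tots)])
      }
    }
    "N"
  }, character(1))
  paste(codes, collapse = "")
}

# Log-odds score matrix (bits) and its integer discretization at the given
# granularity (bits per bin). Shared by the p-value DP and the scanner so
# that scan scores and tail probabilities live on the same grid.
pwm_int_scores <- function(x, granularity) {
  smat <- log2(x$probs / x$background)
  if (any(!is.finite(smat))) {
    # zero-probability cells: effectively -Inf; clamp far below any
    # attainable threshold so DP support stays finite
    smat[!is.finite(smat)] <- min(smat[is.finite(smat)], 0) - 100
  }
  round(smat / granularity)
}

#' Exact null distribution of PWM scores
#'
#' Computes the distribution of the log-odds score of a random word drawn
#' from the background model, by convolving the per-column discrete score
#' distributions on an integer grid of `granularity` bits per bin. The
#' returned table maps scores to exact tail probabilities
#' p(s) = P(score >= s).
#'
#' @param x a [pwm()].
#' @param granularity bin width in bits (default 1e-3).
#' @param max_bins guard against runaway table sizes; widen `granularity`
#'   if exceeded.
#' @return object of class `pwm_pvalue_table`.
#' @export
pwm_pvalue_table <- function(x, granularity = 1e-3, max_bins = 5e7) {
  if (granularity <= 0) stop("granularity must be > 0")
  ints <- pwm_int_scores(x, granularity)
  lo <- sum(apply(ints, 2, min))
  hi <- sum(apply(ints, 2, max))
  if (hi - lo + 1 > max_bins) {
    stop("p-value table would need ", hi - lo + 1,
         " bins; use a coarser granularity")
  }
  dist <- 1
  cur_lo <- 0L
  for (j in seq_len(x$width)) {
    col <- ints[, j]
    new_lo <- cur_lo + min(col)
    new_len <- (cur_lo + max(col)) - new_lo + length(dist)
    new <- numeric(new_len)
    for (b in 1:4) {
      off <- cur_lo + col[b] - new_lo
      idx <- seq_along(dist) + off
      new[idx] <- new[idx] + dist * x$background[b]
    }
    dist <- new
    cur_lo <- new_lo
  }
  if (abs(sum(dist) - 1) > 1e-9) stop("internal: DP mass does not sum to 1")
  surv <- rev(cumsum(rev(dist)))
  structure(list(granularity = granularity, min_int = cur_lo,
                 surv = surv, pwm_width = x$width),
            class = "pwm_pvalue_table")
}

#' Look up exact p-values for scores
#'
#' @param table a [pwm_pvalue_table()].
#' @param score numeric scores in bits (or integer grid scores when
#'   `integer_score = TRUE`).
#' @param integer_score whether `score` is already on the table's grid.
#' @return p-values P(null score >= score).
#' @export
pwm_pvalue <- function(table, score, integer_score = FALSE) {
  k <- if (integer_score) score else round(score / table$granularity)
  idx <- k - table$min_int + 1
  n <- length(table$surv)
  p <- numeric(length(idx))
  p[idx <= 1] <- 1
  p[idx > n] <- 0
  inside <- idx >= 1 & idx <= n
  p[inside] <- table$surv[idx[inside]]
  p
}

# Smallest integer grid score whose tail probability passes the threshold
# (strict < for the stringent scan, <= for the relaxed scan). Returns Inf
# when no attainable score passes.
pwm_score_threshold <- function(table, p_max, strict) {
  pass <- if (strict) table$surv < p_max else table$surv <= p_max
  if (!any(pass)) return(Inf)
  table$min_int + which(pass)[1] - 1
}

# Reverse-complement a PWM (for minus-strand scanning).
pwm_revcomp <- function(x) {
  probs <- x$probs[4:1, x$width:1, drop = FALSE]
  bg <- x$background  # background assumed strand-symmetric is NOT required;
  pwm(probs, background = bg[4:1], pseudocount = x$pseudocount,
      n_sites = x$n_sites)
}

#' Write a motif in MEME minimal format
#'
#' @param x a [pwm()].
#' @param path output path.
#' @param name motif name.
#' @export
write_meme <- function(x, path, name = "motif_1") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               paste(sprintf("%s %.6f", DNA_BASES, x$background),
                     collapse = " "),
               "",
               sprintf("MOTIF %s", name),
               sprintf(
                 "letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                 x$width, max(1L, x$n_sites))), con)
  writeLines(apply(t(x$probs), 1, function(r)
    paste(sprintf("%.6f", r), collapse = "  ")), con)
  invisible(path)
}

#' Read the first motif from a MEME minimal format file
#'
#' @param path MEME motif file.
#' @return a [pwm()].
#' @export
read_meme <- function(path) {
  lines <- readLines(path, warn = FALSE)
  bg <- rep(0.25, 4)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at) > 0) {
    toks <- strsplit(trimws(lines[bg_at[1] + 1]), "\\s+")[[1]]
    bg <- as.numeric(toks[seq(2, 8, by = 2)])
  }
  hdr <- grep("^letter-probability matrix:", lines)
  if (length(hdr) == 0) stop("no letter-probability matrix in ", path)
  w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr[1]]))
  ns <- if (grepl("nsites=", lines[hdr[1]])) {
    as.integer(sub(".*nsites=\\s*(\\d+).*", "\\1", lines[hdr[1]]))
  } else 0L
  rows <- lines[(hdr[1] + 1):(hdr[1] + w)]
  probs <- t(vapply(strsplit(trimws(rows), "\\s+"),
                    function(r) as.numeric(r), numeric(4)))
  probs <- probs / rowSums(probs)  # absorb printed rounding
  pwm(t(probs), background = bg / sum(bg), n_sites = ns)
}

#' Information content per column
#'
#' Relative entropy of each column against the background, in bits.
#'
#' @param x a [pwm()].
#' @return numeric vector, one value per column.
#' @export
pwm_information <- function(x) {
  apply(x$probs, 2, function(p) {
    nz <- p > 0
    sum(p[nz] * log2(p[nz] / x$background[nz]))
  })
}
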