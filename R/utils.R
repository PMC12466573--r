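#' Round half away from zero
#'
#' Rounds to the nearest integer with ties going up (62.5 -> 63), the
#' convention used in the printed per-cluster percentage tables, rather than
#' base R's round-half-even.
#'
#' @param x numeric vector.
#' @return integer vector.
#' @export
round_half_up <- function(x) {
  as.integer(floor(x + 0.5))
}

# Percentage helper: round_half_up(100 * k / n), NA-safe for n == 0.
pct_int <- function(k, n) {
  ifelse(n == 0, NA_integer_, round_half_up(100 * k / n))
}

DNA_BASES <- c("A", "C", "G", "T")

# Encode an ACGTN string as integers 1..4 (NA for N / anything else).
encode_dna <- function(seq) {
  m <- match(strsplit(toupper(seq), "", fixed = TRUE)[[1]], DNA_BASES)
  m
}

decode_dna <- function(idx) {
  paste(DNA_BASES[idx], collapse = "")
}

#' Reverse complement of a DNA string
#'
#' @param seq character scalar over A/C/G/T/N (case-insensitive).
#' @return reverse-complemented uppercase string.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(seq))))
}

# Parse "prefix_NNNNN" locus tags -> list(prefix, suffix). Errors on malformed.
parse_locus_tag <- function(tags) {
  m <- regmatches(tags, regexec("^(.+)_([0-9]+)$", tags))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) {
    stop("malformed locus tag(s): ", paste(tags[bad], collapse = ", "))
  }
  list(
    prefix = vapply(m, `[`, character(1), 2L),
    suffix = as.integer(vapply(m, `[`, character(1), 3L))
  )
}

# Internal: stop unless all conditions hold, with a compact message.
stopifnot_named <- function(...) {
  conds <- list(...)
  for (nm in names(conds)) {
    if (!isTRUE(all(conds[[nm]]))) stop(nm, call. = FALSE)
  }
  invisible(TRUE)
}
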