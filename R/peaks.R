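#' Summit-centred peak post-processing
#'
#' Re-centres each peak on its absolute summit, trims to `summit_flank` bp
#' on each side (201-bp fragments at the default 100), clips at chromosome
#' ends, and keeps only peaks whose fold enrichment is at least
#' `motif_fe_min` (inclusive boundary, default 1.75).
#'
#' @param pk peaks data.frame (see [read_narrowpeak()]).
#' @param cfg a [pipeline_config()].
#' @param chrom_len named chromosome lengths (or a single unnamed length).
#' @return data.frame of summit fragments: chrom, start, end, name,
#'   fold_enrichment.
#' @export
prep_peaks <- function(pk, cfg = pipeline_config(), chrom_len) {
  if (is.null(names(chrom_len))) {
    if (length(unique(pk$chrom)) > 1) {
      stop("chrom_len must be named for multi-chromosome peak sets")
    }
    names(chrom_len) <- unique(pk$chrom)
  }
  len <- chrom_len[pk$chrom]
  if (any(is.na(len))) stop("chrom_len missing for some chromosomes")
  if (any(pk$summit >= len)) stop("summit beyond chromosome end")
  keep <- pk$fold_enrichment >= cfg$motif_fe_min
  pk <- pk[keep, , drop = FALSE]
  len <- len[keep]
  out <- data.frame(
    chrom = pk$chrom,
    start = pmax(0L, pk$summit - cfg$summit_flank),
    end = pmin(as.integer(len), pk$summit + cfg$summit_flank + 1L),
    name = pk$name,
    fold_enrichment = pk$fold_enrichment,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Regions shared between two interval sets
#'
#' A region of `set_a` is shared when some region of `set_b` overlaps it by
#' at least `cfg$shared_min_overlap` nucleotides (default 50), the rule used
#' to compare bound regions between time points.
#'
#' @param set_a,set_b data.frames with chrom, start, end (0-based
#'   half-open). `set_a` must be non-empty.
#' @param cfg a [pipeline_config()].
#' @return list with `pairs` (data.frame of a/b row indices and overlap
#'   widths) and `fraction` of `set_a` shared.
#' @export
shared_regions <- function(set_a, set_b, cfg = pipeline_config()) {
  if (nrow(set_a) == 0) stop("set_a is empty; shared fraction undefined")
  ra <- IRanges::IRanges(set_a$start + 1L, set_a$end)
  rb <- IRanges::IRanges(set_b$start + 1L, set_b$end)
  chrom_a <- if ("chrom" %in% names(set_a)) set_a$chrom else "."
  chrom_b <- if ("chrom" %in% names(set_b)) set_b$chrom else "."
  ov <- IRanges::findOverlaps(ra, rb,
                              minoverlap = cfg$shared_min_overlap)
  qh <- S4Vectors::queryHits(ov)
  sh <- S4Vectors::subjectHits(ov)
  same_chrom <- rep(chrom_a, length.out = nrow(set_a))[qh] ==
    rep(chrom_b, length.out = max(1L, nrow(set_b)))[sh]
  qh <- qh[same_chrom]; sh <- sh[same_chrom]
  widths <- pmin(set_a$end[qh], set_b$end[sh]) -
    pmax(set_a$start[qh], set_b$start[sh])
  list(
    pairs = data.frame(a = qh, b = sh, overlap = widths),
    fraction = length(unique(qh)) / nrow(set_a)
  )
}
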