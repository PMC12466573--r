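#' Strand-aware promoter windows
#'
#' The promoter of a gene is taken as the window from
#' `promoter_upstream` bp upstream through `promoter_downstream` bp
#' downstream of the translational start (so the default 350/50 window covers
#' the start codon). For a forward gene with 0-based start s the window is
#' [s - 350, s + 50); for a reverse gene with end e it is [e - 50, e + 350).
#' Windows are clipped to [0, chrom_len).
#'
#' @param annotation a `gene_annotation` (all strands must be + or -).
#' @param cfg a [pipeline_config()].
#' @param chrom_len named integer vector of chromosome lengths (or a single
#'   length for single-chromosome annotations).
#' @return data.frame with locus_tag, chrom, start, end, strand (the gene's).
#' @export
promoter_window <- function(annotation, cfg = pipeline_config(), chrom_len) {
  if (is.null(names(chrom_len))) {
    if (length(unique(annotation$chrom)) > 1) {
      stop("chrom_len must be named for multi-chromosome annotations")
    }
    names(chrom_len) <- unique(annotation$chrom)
  }
  len <- chrom_len[annotation$chrom]
  if (any(is.na(len))) stop("chrom_len missing for some chromosomes")
  if (any(annotation$end > len) || any(annotation$start < 0)) {
    stop("gene interval outside chromosome")
  }
  up <- cfg$promoter_upstream
  dn <- cfg$promoter_downstream
  fwd <- annotation$strand == "+"
  ws <- ifelse(fwd, annotation$start - up, annotation$end - dn)
  we <- ifelse(fwd, annotation$start + dn, annotation$end + up)
  data.frame(
    locus_tag = annotation$locus_tag,
    chrom = annotation$chrom,
    start = pmax(0L, as.integer(ws)),
    end = pmin(as.integer(len), as.integer(we)),
    strand = annotation$strand,
    stringsAsFactors = FALSE
  )
}

#' Infer putative operons from intergenic distance
#'
#' Heuristic operon model: maximal runs of adjacent genes on the same
#' chromosome and strand whose intergenic gaps are at most
#' `cfg$operon_max_gap` bp. Overlapping same-strand genes count as gap 0
#' (with a warning). Runs of a single gene are not operons.
#'
#' @param annotation a `gene_annotation`, sorted by start within chromosome.
#' @param cfg a [pipeline_config()].
#' @return list of operons; each element is a character vector of locus tags
#'   ordered 5'->3' on the coding strand, with the shared strand as the
#'   `strand` attribute.
#' @export
infer_operons <- function(annotation, cfg = pipeline_config()) {
  out <- list()
  warned <- FALSE
  for (ch in unique(annotation$chrom)) {
    sub <- annotation[annotation$chrom == ch, ]
    sub <- sub[order(sub$start), ]
    if (nrow(sub) < 2) next
    gaps <- sub$start[-1] - sub$end[-nrow(sub)]
    if (any(gaps < 0 & sub$strand[-1] == sub$strand[-nrow(sub)]) && !warned) {
      warning("overlapping same-strand genes treated as gap 0")
      warned <- TRUE
    }
    gaps <- pmax(gaps, 0L)
    linked <- gaps <= cfg$operon_max_gap &
      sub$strand[-1] == sub$strand[-nrow(sub)]
    run_id <- cumsum(c(TRUE, !linked))
    for (id in unique(run_id)) {
      idx <- which(run_id == id)
      if (length(idx) < 2) next
      tags <- sub$locus_tag[idx]
      strand <- sub$strand[idx[1]]
      if (strand == "-") tags <- rev(tags)  # 5'->3' on the coding strand
      out[[length(out) + 1L]] <- structure(tags, strand = strand)
    }
  }
  out
}

#' Genes within a locus-tag range
#'
#' Selects all genes whose locus-tag numeric suffix lies in the closed range
#' [first_tag, last_tag], ordered by suffix — the convention used by
#' cluster tables that give gene ranges such as "vnz_04355-04560".
#'
#' @param first_tag,last_tag locus tags sharing the annotation's prefix.
#' @param annotation a `gene_annotation`.
#' @return the selected rows of `annotation`, ordered by suffix.
#' @export
genes_in_locus_range <- function(first_tag, last_tag, annotation) {
  bounds <- parse_locus_tag(c(first_tag, last_tag))
  if (bounds$prefix[1] != bounds$prefix[2]) {
    stop("range tags have different prefixes: ", first_tag, ", ", last_tag)
  }
  if (bounds$suffix[1] > bounds$suffix[2]) {
    stop("reversed locus range: ", first_tag, " > ", last_tag)
  }
  ann <- parse_locus_tag(annotation$locus_tag)
  hit <- ann$prefix == bounds$prefix[1] &
    ann$suffix >= bounds$suffix[1] & ann$suffix <= bounds$suffix[2]
  if (!any(annotation$locus_tag == first_tag) ||
      !any(annotation$locus_tag == last_tag)) {
    warning("range endpoint tag(s) absent from annotation: ",
            first_tag, "-", last_tag)
  }
  sel <- annotation[hit, ]
  sel <- sel[order(ann$suffix[hit]), ]
  rownames(sel) <- NULL
  sel
}
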