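#' Read a (multi-)FASTA genome
#'
#' @param path FASTA file. Records must be non-empty; sequences are
#'   upper-cased and restricted to A/C/G/T/N.
#' @return named character vector of sequences, record order preserved.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0) stop("empty FASTA file: ", path)
  if (!startsWith(trimws(lines[nonempty[1]]), ">")) {
    stop("malformed FASTA header at line ", nonempty[1], " of ", path)
  }
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0) stop("no records in ", path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  if (any(!nzchar(seqs))) {
    stop("empty sequence record(s): ", paste(names(seqs)[!nzchar(seqs)], collapse = ", "))
  }
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) stop("non-ACGTN characters in record(s): ",
                     paste(names(seqs)[bad], collapse = ", "))
  seqs
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

# Validate and class a gene annotation data.frame (0-based half-open).
gene_annotation <- function(df) {
  need <- c("locus_tag", "chrom", "start", "end", "strand", "product")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) stop("annotation lacks column(s): ", paste(missing, collapse = ", "))
  df <- df[, need]
  if (anyDuplicated(df$locus_tag)) {
    stop("duplicate locus_tag(s): ",
         paste(unique(df$locus_tag[duplicated(df$locus_tag)]), collapse = ", "))
  }
  parse_locus_tag(df$locus_tag)  # errors if unparseable
  if (any(df$start < 0) || any(df$end <= df$start)) {
    stop("invalid gene interval(s): need 0 <= start < end")
  }
  if (!all(df$strand %in% c("+", "-"))) stop("gene strand must be '+' or '-'")
  rownames(df) <- NULL
  class(df) <- c("gene_annotation", "data.frame")
  df
}

#' Read gene records from GFF3
#'
#' Imports `gene` features (falling back to `CDS` when no genes are present)
#' carrying a `locus_tag` attribute. GFF3 1-based inclusive coordinates are
#' converted to the package's internal 0-based half-open convention.
#' Features without a locus_tag are skipped with a warning; duplicate tags
#' are an error.
#'
#' @param path GFF3 file.
#' @return a `gene_annotation` data.frame with columns locus_tag, chrom,
#'   start, end, strand, product.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  keep <- as.character(gr$type) %in% "gene"
  if (!any(keep)) keep <- as.character(gr$type) %in% "CDS"
  gr <- gr[keep]
  if (length(gr) == 0) stop("no gene/CDS features in ", path)
  lt <- if ("locus_tag" %in% names(S4Vectors::mcols(gr))) {
    as.character(gr$locus_tag)
  } else {
    rep(NA_character_, length(gr))
  }
  drop <- is.na(lt) | !nzchar(lt)
  if (any(drop)) {
    warning(sum(drop), " feature(s) without locus_tag skipped")
    gr <- gr[!drop]
    lt <- lt[!drop]
  }
  prod <- if ("product" %in% names(S4Vectors::mcols(gr))) {
    as.character(gr$product)
  } else {
    rep("", length(gr))
  }
  prod[is.na(prod)] <- ""
  gene_annotation(data.frame(
    locus_tag = lt,
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr)),
    product = prod,
    stringsAsFactors = FALSE
  ))
}

#' Write gene records as GFF3
#'
#' Inverse of [read_gff3()]: internal 0-based half-open coordinates are
#' emitted as GFF3 1-based inclusive `gene` features.
#'
#' @param annotation a `gene_annotation`.
#' @param path output path.
#' @export
write_gff3 <- function(annotation, path) {
  header <- "##gff-version 3"
  attrs <- sprintf("ID=%s;locus_tag=%s%s",
                   annotation$locus_tag, annotation$locus_tag,
                   ifelse(nzchar(annotation$product),
                          paste0(";product=", annotation$product), ""))
  lines <- sprintf("%s\tchipregulon\tgene\t%d\t%d\t.\t%s\t.\t%s",
                   annotation$chrom, annotation$start + 1L, annotation$end,
                   annotation$strand, attrs)
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read ENCODE narrowPeak (BED6+4) peaks
#'
#' @param path 10-column narrowPeak file. Column 7 is taken as fold
#'   enrichment, column 9 as -log10(q), column 10 as the summit offset from
#'   `start`. An offset of -1 (summit not called) falls back to the interval
#'   midpoint with a warning; an offset outside the interval is an error.
#' @return data.frame of peaks with absolute `summit`, `fold_enrichment`,
#'   `neg_log10_q`.
#' @export
read_narrowpeak <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          comment.char = "#")
  if (ncol(df) != 10) {
    stop("narrowPeak format error: expected 10 columns, found ", ncol(df))
  }
  names(df) <- c("chrom", "start", "end", "name", "score", "strand",
                 "fold_enrichment", "neg_log10_p", "neg_log10_q", "offset")
  if (any(df$end <= df$start)) stop("invalid peak interval(s)")
  mid <- (df$start + df$end) %/% 2L
  fallback <- df$offset == -1L
  if (any(fallback)) {
    warning(sum(fallback), " peak(s) without summit offset; midpoint used")
  }
  summit <- ifelse(fallback, mid, df$start + df$offset)
  bad <- !fallback & (df$offset < 0L | summit >= df$end)
  if (any(bad)) stop("summit offset outside peak interval for: ",
                     paste(df$name[bad], collapse = ", "))
  peaks(data.frame(
    chrom = df$chrom, start = as.integer(df$start), end = as.integer(df$end),
    name = as.character(df$name), summit = as.integer(summit),
    fold_enrichment = df$fold_enrichment, neg_log10_q = df$neg_log10_q,
    stringsAsFactors = FALSE
  ))
}

# Validate and class a peak data.frame.
peaks <- function(df) {
  need <- c("chrom", "start", "end", "name", "summit", "fold_enrichment",
            "neg_log10_q")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) stop("peaks lack column(s): ", paste(missing, collapse = ", "))
  df <- df[, need]
  if (any(df$start < 0) || any(df$end <= df$start)) stop("invalid peak interval(s)")
  if (any(df$summit < df$start | df$summit >= df$end)) {
    stop("summit outside peak interval")
  }
  if (any(df$fold_enrichment < 0) || any(df$neg_log10_q < 0)) {
    stop("fold_enrichment and neg_log10_q must be >= 0")
  }
  rownames(df) <- NULL
  class(df) <- c("chip_peaks", "data.frame")
  df
}

#' Write peaks as narrowPeak
#'
#' @param pk peaks data.frame (as from [read_narrowpeak()]).
#' @param path output path.
#' @export
write_narrowpeak <- function(pk, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t.\t%.6g\t%.6g\t%.6g\t%d",
                   pk$chrom, pk$start, pk$end, pk$name,
                   pmin(1000L, round_half_up(10 * pk$fold_enrichment)),
                   pk$fold_enrichment, pk$neg_log10_q, pk$neg_log10_q,
                   pk$summit - pk$start)
  writeLines(lines, path)
  invisible(path)
}

#' Write intervals as BED6
#'
#' @param df data.frame with chrom, start, end and optionally name, score,
#'   strand columns (0-based half-open, the BED native convention).
#' @param path output path.
#' @export
write_bed6 <- function(df, path) {
  name <- if ("name" %in% names(df)) df$name else "."
  score <- if ("score" %in% names(df)) df$score else 0
  strand <- if ("strand" %in% names(df)) df$strand else "."
  writeLines(sprintf("%s\t%d\t%d\t%s\t%.6g\t%s",
                     df$chrom, df$start, df$end, name, score, strand), path)
  invisible(path)
}

#' Read a gene-level count matrix (TSV)
#'
#' First column = locus tags, remaining columns = samples.
#'
#' @param path TSV path with a header row of sample names.
#' @return integer matrix, genes x samples.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  if (any(is.na(m)) || any(m < 0)) stop("counts must be non-negative integers")
  m
}

#' Write a count matrix as TSV
#'
#' @param counts genes x samples matrix with rownames.
#' @param path output path.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(locus_tag = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
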