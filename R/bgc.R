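#' Load a biosynthetic-gene-cluster definition table
#'
#' TSV with columns bgc_id, bgc_type, first_tag, last_tag (and optionally
#' product), one row per cluster, locus-tag ranges as printed in
#' antiSMASH-style cluster tables. Ranges are validated against the
#' annotation; overlapping ranges are rejected unless
#' `allow_overlap = TRUE`.
#'
#' @param path TSV path.
#' @param annotation a `gene_annotation` to validate against.
#' @param allow_overlap permit overlapping cluster ranges.
#' @return data.frame of BGC records with an `n_genes` column.
#' @export
load_bgc_table <- function(path, annotation, allow_overlap = FALSE) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("bgc_id", "bgc_type", "first_tag", "last_tag")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) stop("BGC table lacks column(s): ",
                                paste(missing, collapse = ", "))
  if (!"product" %in% names(df)) df$product <- ""
  ft <- parse_locus_tag(df$first_tag)
  lt <- parse_locus_tag(df$last_tag)
  bad <- ft$suffix > lt$suffix
  if (any(bad)) stop("reversed locus range in BGC row(s): ",
                     paste(df$bgc_id[bad], collapse = ", "))
  prefix <- unique(parse_locus_tag(annotation$locus_tag)$prefix)
  if (any(!ft$prefix %in% prefix)) {
    stop("BGC tag prefix does not match the annotation")
  }
  o <- order(ft$suffix)
  if (!allow_overlap && nrow(df) > 1) {
    if (any(ft$suffix[o][-1] <= lt$suffix[o][-nrow(df)])) {
      stop("overlapping BGC ranges; pass allow_overlap = TRUE to keep them")
    }
  }
  df$n_genes <- vapply(seq_len(nrow(df)), function(i) {
    nrow(genes_in_locus_range(df$first_tag[i], df$last_tag[i], annotation))
  }, integer(1))
  df
}

#' Summarize one BGC's expression response and binding sites
#'
#' Per time point, the percentage of cluster genes down- and upregulated
#' (round-half-up integers) and a strong-response flag set when strictly
#' more than `cfg$strong_response_frac` of the cluster's genes are
#' differentially expressed. `n_sites` counts raw motif occurrences whose
#' interval lies wholly within the cluster's genomic span (first gene start
#' to last gene end) — binding evidence before any promoter assignment.
#'
#' @param bgc one row of the table from [load_bgc_table()].
#' @param annotation a `gene_annotation`.
#' @param degs_by_tp named list of classified DEG tables, one per time
#'   point.
#' @param hits motif-hit data.frame in genome coordinates (may be NULL).
#' @param cfg a [pipeline_config()].
#' @return one-row data.frame: bgc_id, n_genes, then pct_down/pct_up/
#'   strong_response per time point, n_sites.
#' @export
bgc_summary <- function(bgc, annotation, degs_by_tp, hits = NULL,
                        cfg = pipeline_config()) {
  members <- genes_in_locus_range(bgc$first_tag, bgc$last_tag, annotation)
  if (nrow(members) == 0) stop("BGC ", bgc$bgc_id, " has no genes in the annotation")
  out <- data.frame(bgc_id = bgc$bgc_id, bgc_type = bgc$bgc_type,
                    n_genes = nrow(members), stringsAsFactors = FALSE)
  for (tp in names(degs_by_tp)) {
    d <- degs_by_tp[[tp]]
    st <- d$status[match(members$locus_tag, d$locus_tag)]
    st[is.na(st)] <- "ns"
    n_down <- sum(st == "down")
    n_up <- sum(st == "up")
    if ((n_down + n_up) / nrow(members) > 1 + 1e-12) {
      stop("internal: DEG fraction above 1 in BGC ", bgc$bgc_id)
    }
    out[[paste0("pct_down_", tp)]] <- round_half_up(100 * n_down / nrow(members))
    out[[paste0("pct_up_", tp)]] <- round_half_up(100 * n_up / nrow(members))
    out[[paste0("strong_response_", tp)]] <-
      (n_down + n_up) / nrow(members) > cfg$strong_response_frac
  }
  span_start <- min(members$start)
  span_end <- max(members$end)
  ch <- members$chrom[1]
  out$n_sites <- if (is.null(hits) || nrow(hits) == 0) 0L else {
    sum(hits$chrom == ch & hits$start >= span_start & hits$end <= span_end)
  }
  out
}

#' Summarize every BGC
#'
#' @param bgc_table table from [load_bgc_table()].
#' @param annotation,degs_by_tp,hits,cfg see [bgc_summary()].
#' @return data.frame, one row per cluster.
#' @export
bgc_report <- function(bgc_table, annotation, degs_by_tp, hits = NULL,
                       cfg = pipeline_config()) {
  rows <- lapply(seq_len(nrow(bgc_table)), function(i) {
    bgc_summary(bgc_table[i, ], annotation, degs_by_tp, hits, cfg)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Count strong-response clusters per time point
#'
#' @param summaries data.frame from [bgc_report()].
#' @return named integer vector, one count per time point.
#' @export
count_strong_responses <- function(summaries) {
  cols <- grep("^strong_response_", names(summaries), value = TRUE)
  out <- vapply(cols, function(cl) sum(summaries[[cl]]), integer(1))
  names(out) <- sub("^strong_response_", "", cols)
  out
}

#' Hypergeometric over-representation analysis
#'
#' One-sided hypergeometric tail test of pathway membership in a gene set
#' (a deliberately simple stand-in for rank-based set enrichment):
#' p = P(X >= k) with k = |set ∩ pathway|, K = |pathway|, n = |set|,
#' N = |universe|; q by Benjamini-Hochberg across pathways.
#'
#' @param gene_set character vector, a subset of `universe`.
#' @param pathway_map named list: pathway label -> member genes.
#' @param universe character vector of all genes.
#' @return data.frame with pathway, overlap, size, p, q.
#' @export
ora_enrichment <- function(gene_set, pathway_map, universe) {
  if (length(gene_set) == 0) stop("empty gene set")
  if (!all(gene_set %in% universe)) stop("gene_set must be within universe")
  if (length(pathway_map) == 0) stop("no pathways")
  N <- length(unique(universe))
  n <- length(unique(gene_set))
  rows <- lapply(names(pathway_map), function(pw) {
    members <- intersect(pathway_map[[pw]], universe)
    k <- length(intersect(gene_set, members))
    K <- length(members)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway = pw, overlap = k, size = K, p = min(1, p),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  rownames(out) <- NULL
  out
}

#' Render the per-cluster report to disk
#'
#' Writes the cluster-table-shaped TSV plus a machine-readable JSON twin
#' bundling the cluster summaries, the direct-regulon entries, and the DEG
#' summary. Output is deterministic: identical inputs give byte-identical
#' files.
#'
#' @param summaries data.frame from [bgc_report()].
#' @param regulon `entries` from [build_direct_regulon()] (may be empty).
#' @param deg_sum result of [deg_summary()].
#' @param dir output directory (created if needed).
#' @return invisible named vector of written paths.
#' @export
render_report <- function(summaries, regulon, deg_sum, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tsv <- file.path(dir, "bgc_report.tsv")
  utils::write.table(summaries, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  json <- file.path(dir, "bgc_report.json")
  payload <- list(bgc_summaries = summaries,
                  direct_regulon = regulon,
                  deg_summary = deg_sum,
                  n_regulon_entries = nrow(regulon))
  jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(c(tsv = tsv, json = json))
}
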