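#' Assign motif hits to promoter windows
#'
#' A hit is assigned to every gene whose promoter window it overlaps by at
#' least 1 nt (or fully contains it with `full_containment = TRUE`). A hit
#' in the shared region of a divergent gene pair is therefore assigned to
#' both genes.
#'
#' @param hits motif-hit data.frame (genome coordinates, see
#'   [scan_intervals()]).
#' @param windows promoter windows from [promoter_window()].
#' @param full_containment require the hit to lie wholly inside the window.
#' @return list with `assignments` (data.frame hit/locus_tag, one row per
#'   hit-gene pair) and `unassigned` (hit row indices overlapping no
#'   window).
#' @export
assign_hits_to_promoters <- function(hits, windows,
                                     full_containment = FALSE) {
  if (nrow(hits) == 0) {
    return(list(assignments = data.frame(hit = integer(),
                                         locus_tag = character()),
                unassigned = integer()))
  }
  pairs <- list()
  for (ch in unique(hits$chrom)) {
    hi <- which(hits$chrom == ch)
    wi <- which(windows$chrom == ch)
    if (length(wi) == 0) next
    rh <- IRanges::IRanges(hits$start[hi] + 1L, hits$end[hi])
    rw <- IRanges::IRanges(windows$start[wi] + 1L, windows$end[wi])
    ov <- IRanges::findOverlaps(rh, rw,
                                type = if (full_containment) "within" else "any")
    if (length(ov) == 0) next
    pairs[[length(pairs) + 1L]] <- data.frame(
      hit = hi[S4Vectors::queryHits(ov)],
      locus_tag = windows$locus_tag[wi[S4Vectors::subjectHits(ov)]],
      stringsAsFactors = FALSE)
  }
  assignments <- if (length(pairs) > 0) do.call(rbind, pairs) else {
    data.frame(hit = integer(), locus_tag = character())
  }
  assignments <- assignments[order(assignments$hit, assignments$locus_tag), ]
  rownames(assignments) <- NULL
  list(assignments = assignments,
       unassigned = setdiff(seq_len(nrow(hits)), assignments$hit))
}

#' Operon-aware attribution of promoter hits
#'
#' When a single hit is assigned to two or more genes of the same operon,
#' only the gene whose start codon is nearest the hit midpoint is kept
#' (distance = |hit midpoint - start codon|; exact ties go to the smaller
#' locus suffix and are logged). Genes outside operons are untouched.
#' Removed pairs are returned as putatively co-regulated downstream
#' members.
#'
#' @param assignment result of [assign_hits_to_promoters()].
#' @param hits the hit data.frame the assignment indexes into.
#' @param operons operon list from [infer_operons()] (or curated).
#' @param annotation the `gene_annotation` (for start-codon positions).
#' @return list with filtered `assignments` and `co_regulated` (the dropped
#'   hit-gene pairs).
#' @export
operon_attribution <- function(assignment, hits, operons, annotation) {
  asg <- assignment$assignments
  if (nrow(asg) == 0) {
    return(list(assignments = asg,
                co_regulated = asg, unassigned = assignment$unassigned))
  }
  op_of <- rep(NA_integer_, nrow(annotation))
  names(op_of) <- annotation$locus_tag
  for (i in seq_along(operons)) op_of[operons[[i]]] <- i
  start_codon <- ifelse(annotation$strand == "+", annotation$start,
                        annotation$end - 1L)
  names(start_codon) <- annotation$locus_tag

  keep <- rep(TRUE, nrow(asg))
  mid <- (hits$start + hits$end) / 2
  suffix <- parse_locus_tag(asg$locus_tag)$suffix
  for (h in unique(asg$hit)) {
    rows <- which(asg$hit == h)
    ops <- op_of[asg$locus_tag[rows]]
    for (o in unique(ops[!is.na(ops)])) {
      grp <- rows[!is.na(ops) & ops == o]
      if (length(grp) < 2) next
      d <- abs(mid[h] - start_codon[asg$locus_tag[grp]])
      best <- grp[d == min(d)]
      if (length(best) > 1) {
        message("operon distance tie at hit ", h, "; smaller suffix kept")
        best <- best[which.min(suffix[best])]
      }
      keep[setdiff(grp, best)] <- FALSE
    }
  }
  list(assignments = asg[keep, , drop = FALSE],
       co_regulated = asg[!keep, , drop = FALSE],
       unassigned = assignment$unassigned)
}

#' Build the direct regulon
#'
#' One entry per gene that both carries at least one promoter-assigned
#' motif hit (after operon attribution) and is differentially expressed.
#' Genes down in the deletion mutant are regulator-activated
#' (mode "activated"); genes up are "repressed". Bound but non-significant
#' genes are reported separately.
#'
#' @param attribution result of [operon_attribution()] (or of
#'   [assign_hits_to_promoters()] when no operon filtering is wanted).
#' @param hits the hit data.frame the assignments index into.
#' @param degs classified DEG table (see [classify_degs()]).
#' @return list with `entries` (data.frame locus_tag, n_hits, best_p,
#'   log2fc, fdr, deg_status, mode) and `bound_only` (bound genes with
#'   status ns or absent from the DE table).
#' @export
build_direct_regulon <- function(attribution, hits, degs) {
  asg <- attribution$assignments
  if (nrow(asg) == 0) {
    empty <- data.frame(locus_tag = character(), n_hits = integer(),
                        best_p = numeric(), log2fc = numeric(),
                        fdr = numeric(), deg_status = character(),
                        mode = character(), stringsAsFactors = FALSE)
    return(list(entries = empty, bound_only = character()))
  }
  by_gene <- split(asg$hit, asg$locus_tag)
  bound <- data.frame(
    locus_tag = names(by_gene),
    n_hits = lengths(by_gene),
    best_p = vapply(by_gene, function(i) min(hits$p_value[i]), numeric(1)),
    stringsAsFactors = FALSE)
  i <- match(bound$locus_tag, degs$locus_tag)
  status <- ifelse(is.na(i), "ns", degs$status[i])
  entries <- bound[status %in% c("up", "down"), , drop = FALSE]
  ii <- match(entries$locus_tag, degs$locus_tag)
  entries$log2fc <- degs$log2fc[ii]
  entries$fdr <- degs$fdr[ii]
  entries$deg_status <- degs$status[ii]
  entries$mode <- ifelse(entries$deg_status == "down", "activated",
                         "repressed")
  entries <- entries[order(entries$locus_tag), ]
  rownames(entries) <- NULL
  list(entries = entries,
       bound_only = sort(bound$locus_tag[!status %in% c("up", "down")]))
}

#' Direct-regulon summary across two time points
#'
#' @param entries_t1,entries_t2 `entries` tables from
#'   [build_direct_regulon()].
#' @param degs_t1,degs_t2 the matching classified DEG tables.
#' @return list with per-time-point regulon sizes, activated fractions and
#'   shares of total DEGs (round-half-up integer percent; NA when empty),
#'   and the shared-gene count.
#' @export
regulon_summary <- function(entries_t1, entries_t2, degs_t1, degs_t2) {
  one <- function(entries, degs) {
    n_deg <- sum(degs$status != "ns")
    list(n_entries = nrow(entries),
         n_activated = sum(entries$mode == "activated"),
         pct_activated = pct_int(sum(entries$mode == "activated"),
                                 nrow(entries)),
         pct_of_degs = pct_int(nrow(entries), n_deg))
  }
  list(
    t1 = one(entries_t1, degs_t1),
    t2 = one(entries_t2, degs_t2),
    n_shared = length(intersect(entries_t1$locus_tag, entries_t2$locus_tag))
  )
}

#' Relaxed-threshold regulon sets
#'
#' For a relaxed genome-wide scan (p <= `relaxed_p_max`), returns the
#' nested gene sets: promoter-bound at the relaxed threshold, that set
#' intersected with DEGs, and (when supplied) the stringent direct regulon,
#' whose membership in the relaxed intersection is asserted.
#'
#' @param relaxed_hits hits from the relaxed genome scan.
#' @param windows promoter windows.
#' @param degs classified DEG table.
#' @param stringent_entries optional `entries` from
#'   [build_direct_regulon()] on the stringent scan.
#' @return list with `bound`, `bound_deg`, `stringent` character vectors.
#' @export
relaxed_regulon <- function(relaxed_hits, windows, degs,
                            stringent_entries = NULL) {
  asg <- assign_hits_to_promoters(relaxed_hits, windows)$assignments
  bound <- sort(unique(asg$locus_tag))
  deg_tags <- degs$locus_tag[degs$status != "ns"]
  bound_deg <- intersect(bound, deg_tags)
  stringent <- if (is.null(stringent_entries)) character() else {
    stringent_entries$locus_tag
  }
  if (length(stringent) > 0 && !all(stringent %in% bound_deg)) {
    stop("stringent regulon is not nested in the relaxed bound-DEG set; ",
         "were the scans run with different windows or PWMs?")
  }
  list(bound = bound, bound_deg = sort(bound_deg),
       stringent = sort(stringent))
}
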