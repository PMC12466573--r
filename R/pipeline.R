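#' End-to-end direct-regulon inference
#'
#' Runs the full integration on in-memory objects: peak post-processing
#' ([prep_peaks()]), motif discovery on the summit fragments
#' ([em_discover()], unless a motif is supplied), a stringent exact-p-value
#' scan of the fragments ([scan_intervals()], p < `cfg$scan_p_max`),
#' promoter-window assignment with operon-aware attribution, DEG
#' classification through the fold-change-threshold NB test, and direct
#' regulon construction. Optionally also performs the relaxed genome-wide
#' scan (p <= `cfg$relaxed_p_max`) and the nested relaxed sets.
#'
#' @param genome named character vector of chromosome sequences.
#' @param annotation a `gene_annotation`.
#' @param pk peaks data.frame.
#' @param counts genes x samples count matrix.
#' @param groups two-level factor over samples, reference level first.
#' @param cfg a [pipeline_config()].
#' @param motif optional known [pwm()]; skips discovery when given.
#' @param operons optional curated operon list; inferred by
#'   [infer_operons()] otherwise.
#' @param restarts,seed passed to [em_discover()].
#' @param relaxed also run the relaxed genome-wide scan.
#' @return list with motif, fragments, hits, windows, operons, de table,
#'   degs, regulon (entries + bound_only), and (when `relaxed`) the
#'   relaxed hit/gene sets.
#' @export
infer_regulon <- function(genome, annotation, pk, counts, groups,
                          cfg = pipeline_config(), motif = NULL,
                          operons = NULL, restarts = 8L, seed = 1L,
                          relaxed = FALSE) {
  chrom_len <- stats::setNames(nchar(genome), names(genome))
  fragments <- prep_peaks(pk, cfg, chrom_len)
  if (is.null(motif)) {
    frag_seqs <- extract_sequences(genome, fragments)
    disc <- em_discover(frag_seqs, cfg$motif_width, restarts = restarts,
                        seed = seed)
    motif <- disc$pwm
  } else {
    disc <- NULL
  }
  table <- pwm_pvalue_table(motif)
  hits <- scan_intervals(motif, genome, fragments, p_max = cfg$scan_p_max,
                         strict = TRUE, table = table)
  windows <- promoter_window(annotation, cfg, chrom_len)
  if (is.null(operons)) operons <- infer_operons(annotation, cfg)
  assignment <- assign_hits_to_promoters(hits, windows)
  attribution <- operon_attribution(assignment, hits, operons, annotation)
  de <- treat_test(counts, groups, cfg)
  degs <- classify_degs(de, cfg)
  regulon <- build_direct_regulon(attribution, hits, degs)
  out <- list(motif = motif, discovery = disc, fragments = fragments,
              hits = hits, windows = windows, operons = operons,
              attribution = attribution, de = de, degs = degs,
              regulon = regulon)
  if (relaxed) {
    genome_df <- data.frame(chrom = names(genome), start = 0L,
                            end = unname(nchar(genome)),
                            stringsAsFactors = FALSE)
    out$relaxed_hits <- scan_intervals(motif, genome, genome_df,
                                       p_max = cfg$relaxed_p_max,
                                       strict = FALSE, table = table)
    out$relaxed <- relaxed_regulon(out$relaxed_hits, windows, degs,
                                   regulon$entries)
  }
  out
}

#' Score an inferred regulon against synthetic truth
#'
#' @param entries `entries` from [build_direct_regulon()].
#' @param truth a `synthetic_truth`.
#' @return list with precision, recall, and the two gene-set differences.
#' @export
score_regulon <- function(entries, truth) {
  called <- entries$locus_tag
  real <- truth$direct_targets
  tp <- length(intersect(called, real))
  list(
    precision = if (length(called) == 0) NA_real_ else tp / length(called),
    recall = if (length(real) == 0) NA_real_ else tp / length(real),
    false_positives = setdiff(called, real),
    missed = setdiff(real, called)
  )
}
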