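#' Pipeline configuration
#'
#' Bundles every threshold the integration pipeline uses. Defaults are the
#' published operating point of the workflow: differential expression calls
#' require fold change >= 1.5 at FDR < 0.05; ChIP peaks enter motif discovery
#' only when their fold enrichment is >= 1.75, after being re-centred on the
#' summit and trimmed to 100 bp on each side (201-bp fragments); promoter
#' windows run from 350 bp upstream to 50 bp downstream of the translational
#' start; the stringent motif scan uses p < 1e-4 (strict) while the relaxed
#' genome-wide scan uses p <= 1.04e-4; regions are "shared" between time
#' points at >= 50 nt overlap; and a biosynthetic gene cluster shows a strong
#' response when strictly more than 50% of its genes are differentially
#' expressed.
#'
#' @param deg_fc_min minimum fold change (linear scale) for a DEG call.
#' @param deg_fdr_max FDR ceiling for a DEG call (strict <).
#' @param peak_q_max q-value ceiling for peak significance.
#' @param peak_fc_min minimum peak fold change for significance.
#' @param motif_fe_min fold-enrichment floor (inclusive) for peaks entering
#'   motif discovery.
#' @param summit_flank bp kept on each side of the summit (201-bp fragments
#'   at the default 100).
#' @param shared_min_overlap minimum nt overlap for two regions to count as
#'   shared.
#' @param promoter_upstream,promoter_downstream promoter window extent in bp
#'   relative to the start codon.
#' @param scan_p_max stringent scan p-value threshold (strict <).
#' @param relaxed_p_max relaxed scan p-value threshold (inclusive <=).
#' @param motif_width motif width in bp.
#' @param strong_response_frac DEG fraction a cluster must strictly exceed to
#'   be flagged as a strong response.
#' @param operon_max_gap maximum intergenic gap (bp) joining same-strand
#'   neighbours into an operon (heuristic; substitute curated operons where
#'   available).
#' @param low_count_min genes with fewer total reads than this across all
#'   libraries are dropped before normalization.
#' @param rng_seed integer seed recorded with the configuration.
#' @return object of class `pipeline_config` (a validated named list).
#' @export
pipeline_config <- function(deg_fc_min = 1.5,
                            deg_fdr_max = 0.05,
                            peak_q_max = 0.05,
                            peak_fc_min = 1.5,
                            motif_fe_min = 1.75,
                            summit_flank = 100L,
                            shared_min_overlap = 50L,
                            promoter_upstream = 350L,
                            promoter_downstream = 50L,
                            scan_p_max = 1e-4,
                            relaxed_p_max = 1.04e-4,
                            motif_width = 15L,
                            strong_response_frac = 0.5,
                            operon_max_gap = 50L,
                            low_count_min = 10L,
                            rng_seed = 1L) {
  cfg <- list(
    deg_fc_min = deg_fc_min, deg_fdr_max = deg_fdr_max,
    peak_q_max = peak_q_max, peak_fc_min = peak_fc_min,
    motif_fe_min = motif_fe_min, summit_flank = as.integer(summit_flank),
    shared_min_overlap = as.integer(shared_min_overlap),
    promoter_upstream = as.integer(promoter_upstream),
    promoter_downstream = as.integer(promoter_downstream),
    scan_p_max = scan_p_max, relaxed_p_max = relaxed_p_max,
    motif_width = as.integer(motif_width),
    strong_response_frac = strong_response_frac,
    operon_max_gap = as.integer(operon_max_gap),
    low_count_min = as.integer(low_count_min),
    rng_seed = as.integer(rng_seed)
  )
  num <- vapply(cfg, is.numeric, logical(1))
  if (!all(num)) stop("all configuration fields must be numeric")
  thresholds <- setdiff(names(cfg), "rng_seed")
  if (any(unlist(cfg[thresholds]) <= 0)) {
    stop("all thresholds must be > 0")
  }
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pipeline_config:\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Read a pipeline configuration file
#'
#' Accepts either a JSON object or a flat `key: value` file (one field per
#' line, `#` comments allowed) whose keys mirror [pipeline_config()] argument
#' names exactly. Unknown keys are an error.
#'
#' @param path path to the configuration file.
#' @return a `pipeline_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  txt <- readLines(path, warn = FALSE)
  if (length(txt) > 0 && grepl("^\\s*\\{", txt[1])) {
    vals <- jsonlite::fromJSON(paste(txt, collapse = "\n"))
  } else {
    txt <- sub("#.*$", "", txt)
    txt <- trimws(txt)
    txt <- txt[nzchar(txt)]
    kv <- regmatches(txt, regexec("^([A-Za-z_]+)\\s*:\\s*(\\S+)$", txt))
    bad <- vapply(kv, length, integer(1)) != 3L
    if (any(bad)) stop("malformed config line(s): ", paste(txt[bad], collapse = "; "))
    vals <- as.list(as.numeric(vapply(kv, `[`, character(1), 3L)))
    names(vals) <- vapply(kv, `[`, character(1), 2L)
  }
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}
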