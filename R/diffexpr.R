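#' TMM normalization factors
#'
#' Trimmed mean of M-values between-sample normalization for count data:
#' per sample, M (log2 ratio) and A (log2 abundance) values against a
#' reference sample are trimmed (30% each side on M, 5% each side on A) and
#' the precision-weighted mean M gives the log2 factor. Factors are rescaled
#' to geometric mean 1. The reference sample is the one whose upper-quartile
#' scaled count is closest to the mean upper quartile.
#'
#' @param counts non-negative integer matrix, genes x samples (>= 2
#'   samples, none all-zero).
#' @param logratio_trim,sum_trim two-sided trim fractions on M and A.
#' @return numeric vector of per-sample factors, geometric mean 1.
#' @export
tmm_factors <- function(counts, logratio_trim = 0.3, sum_trim = 0.05) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("need >= 2 samples")
  if (any(counts < 0)) stop("counts must be non-negative")
  lib <- colSums(counts)
  if (any(lib == 0)) stop("all-zero sample(s)")
  uq <- apply(counts, 2, function(x) stats::quantile(x[x > 0], 0.75)) / lib
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    if (j == ref) return(1)
    tmm_pair(counts[, j], counts[, ref], lib[j], lib[ref],
             logratio_trim, sum_trim)
  }, numeric(1))
  f / exp(mean(log(f)))
}

# One-pair TMM: weighted trimmed mean of M against the reference.
tmm_pair <- function(obs, ref, n_obs, n_ref, logratio_trim, sum_trim) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  m <- log2((obs / n_obs) / (ref / n_ref))
  a <- 0.5 * log2((obs / n_obs) * (ref / n_ref))
  # delta-method precision weights for the binomial log-ratio
  w <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  fin <- is.finite(m) & is.finite(a) & abs(a) < 1e10
  m <- m[fin]; a <- a[fin]; w <- w[fin]
  n <- length(m)
  if (n == 0) return(1)
  lo_m <- floor(n * logratio_trim) + 1
  hi_m <- n + 1 - lo_m
  lo_a <- floor(n * sum_trim) + 1
  hi_a <- n + 1 - lo_a
  keep <- rank(m, ties.method = "first") >= lo_m &
    rank(m, ties.method = "first") <= hi_m &
    rank(a, ties.method = "first") >= lo_a &
    rank(a, ties.method = "first") <= hi_a
  if (!any(keep)) return(1)
  2^(sum(m[keep] / w[keep]) / sum(1 / w[keep]))
}

#' Fold-change-threshold negative-binomial test
#'
#' A documented stand-in for a quasi-likelihood fold-change-threshold test
#' of H0: |log2 fold change| <= log2(`cfg$deg_fc_min`). Per gene, a
#' negative-binomial model with a log link and effective-library-size
#' offsets (TMM-normalized) is fitted with the group effect free and with
#' it constrained to each threshold boundary; the signed square roots of
#' the two deviance differences form the test statistic. The tagwise
#' method-of-moments dispersion is shrunk towards the common value with
#' `prior_df` pseudo-degrees of freedom (at 3 vs 3 the tagwise estimate
#' has only 4 residual df, so the common value dominates, mirroring
#' empirical-Bayes dispersion moderation).
#'
#' Two null conventions are offered. `"interval"` (default) averages the
#' rejection probability over the whole null interval, the convention of
#' modern threshold tests, and is noticeably more powerful near the
#' boundary. `"worst.case"` sums the two boundary tails; under it, genes
#' whose observed |log2fc| is at or below the threshold receive p >= 0.5
#' by construction. Genes with fewer than `cfg$low_count_min` reads in
#' total across all libraries are excluded before normalization.
#'
#' @param counts genes x samples integer matrix with locus tags as
#'   rownames.
#' @param groups factor/character of length ncol(counts) with exactly two
#'   levels; the first level is the reference (e.g. the complemented
#'   strain), so log2fc is level 2 (e.g. the deletion mutant) relative to
#'   level 1.
#' @param cfg a [pipeline_config()].
#' @param prior_df pseudo-df of the common dispersion in the shrinkage
#'   blend; the tagwise estimate is weighted by its residual df.
#' @param null null convention, `"interval"` or `"worst.case"`.
#' @return data.frame with locus_tag, log2fc, p_value, dispersion for every
#'   retained gene.
#' @export
treat_test <- function(counts, groups, cfg = pipeline_config(),
                       prior_df = 20, null = c("interval", "worst.case")) {
  null <- match.arg(null)
  counts <- as.matrix(counts)
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("need exactly 2 groups")
  if (any(table(groups) < 2)) stop("need >= 2 replicates per group")
  if (length(groups) != ncol(counts)) stop("groups length != n samples")
  keep <- rowSums(counts) >= cfg$low_count_min
  counts <- counts[keep, , drop = FALSE]
  if (nrow(counts) == 0) stop("no genes pass the low-count filter")

  eff <- colSums(counts) * tmm_factors(counts)
  off <- log(eff / exp(mean(log(eff))))     # per-sample log offsets
  norm <- sweep(counts, 2, exp(-off), `*`)
  g1 <- groups == levels(groups)[1]
  g2 <- !g1
  n1 <- sum(g1); n2 <- sum(g2)
  m1 <- rowMeans(norm[, g1, drop = FALSE])
  m2 <- rowMeans(norm[, g2, drop = FALSE])
  v1 <- apply(norm[, g1, drop = FALSE], 1, stats::var)
  v2 <- apply(norm[, g2, drop = FALSE], 1, stats::var)

  # tagwise MoM dispersion pooled over groups, shrunk towards the common
  # one with df weighting (tagwise df vs prior_df)
  num <- (n1 - 1) * (v1 - m1) + (n2 - 1) * (v2 - m2)
  den <- (n1 - 1) * m1^2 + (n2 - 1) * m2^2
  disp_tag <- pmax(0, num / pmax(den, 1e-8))
  disp_common <- mean(disp_tag, trim = 0.1)
  df_tag <- (n1 - 1) + (n2 - 1)
  w <- df_tag / (df_tag + prior_df)
  disp <- pmax(1e-8, w * disp_tag + (1 - w) * disp_common)

  # vectorized one-parameter NB-GLM fits (log link, fixed dispersion)
  ll <- function(Y, MU) {
    a <- disp
    rowSums(lgamma(Y + 1 / a) - lgamma(1 / a) - lgamma(Y + 1) +
              Y * log(a * MU / (1 + a * MU)) - (1 / a) * log(1 + a * MU))
  }
  fit_mean <- function(Y, o) {
    # per-gene MLE of theta in mu_j = exp(theta + o_j)
    theta <- log(pmax(rowMeans(sweep(Y, 2, exp(-o), `*`)), 1e-8))
    for (it in 1:50) {
      MU <- exp(outer(theta, o, `+`))
      f <- rowSums((Y - MU) / (1 + disp * MU))
      fp <- -rowSums(MU * (1 + disp * Y) / (1 + disp * MU)^2)
      step <- f / fp
      step <- pmin(pmax(step, -2), 2)
      theta <- pmax(theta - step, -15)
      if (max(abs(step)) < 1e-10) break
    }
    theta
  }
  Y1 <- counts[, g1, drop = FALSE]
  Y2 <- counts[, g2, drop = FALSE]
  th1 <- fit_mean(Y1, off[g1])
  th2 <- fit_mean(Y2, off[g2])
  l_alt <- ll(Y1, exp(outer(th1, off[g1], `+`))) +
    ll(Y2, exp(outer(th2, off[g2], `+`)))
  beta <- th2 - th1
  lfc <- beta / log(2)
  tau_n <- log(cfg$deg_fc_min)

  boundary_z <- function(b) {
    # constrained fit: beta fixed at b, intercept free (absorb b into the
    # offsets of group 2)
    o_adj <- off
    o_adj[g2] <- o_adj[g2] + b
    th0 <- fit_mean(counts, o_adj)
    MU0 <- exp(outer(th0, o_adj, `+`))
    l_null <- ll(counts, MU0)
    sqrt(pmax(0, 2 * (l_alt - l_null)))
  }
  z_pos <- boundary_z(tau_n)
  z_neg <- boundary_z(-tau_n)
  z_right <- pmax(z_pos, z_neg)   # far boundary
  z_left <- pmin(z_pos, z_neg)    # near boundary
  within <- abs(lfc) <= log2(cfg$deg_fc_min)
  z_left <- z_left * (2 * within - 1)  # negative when outside H0

  if (null == "interval") {
    # null effect averaged over the threshold interval (width constant as
    # in published threshold tests)
    cc <- 1.470402
    integrate_pnorm <- function(a, b) {
      ifelse(abs(b - a) < 1e-12, stats::pnorm(a),
             (b * stats::pnorm(b) + stats::dnorm(b) -
                (a * stats::pnorm(a) + stats::dnorm(a))) / (b - a))
    }
    p <- ifelse(z_right + z_left > cc,
                integrate_pnorm(-z_right, -z_right + cc) +
                  integrate_pnorm(z_left - cc, z_left),
                2 * integrate_pnorm(-z_right, z_left))
  } else {
    p <- stats::pnorm(-z_right) + stats::pnorm(z_left)
  }
  p <- pmin(1, pmax(p, .Machine$double.xmin))
  data.frame(locus_tag = rownames(counts), log2fc = lfc, p_value = p,
             dispersion = disp, row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up FDR
#'
#' q_(i) = min over j >= i of p_(j) * m / j on the sorted p-values, mapped
#' back to input order. Elementwise q >= p and monotone in p.
#'
#' @param p_values vector of p-values in (0, 1].
#' @return q-values in input order.
#' @export
bh_fdr <- function(p_values) {
  m <- length(p_values)
  if (m == 0) stop("empty p-value vector")
  if (any(is.na(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    stop("p-values must be in (0, 1]")
  }
  o <- order(p_values)
  q_sorted <- rev(cummin(rev(p_values[o] * m / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(1, q_sorted)
  q
}

#' Classify genes as up / down / ns
#'
#' A gene is `down` when its fold change is at least `cfg$deg_fc_min`
#' (inclusive, on the linear scale), its FDR is strictly below
#' `cfg$deg_fdr_max`, and log2fc < 0; `up` symmetrically; otherwise `ns`.
#' With the mutant-vs-complemented sign convention, `down` genes are the
#' regulator-activated ones.
#'
#' @param table data.frame with locus_tag, log2fc and either `fdr` or
#'   `p_value` (FDR computed with [bh_fdr()] in the latter case).
#' @param cfg a [pipeline_config()].
#' @return data.frame with locus_tag, log2fc, p_value (if present), fdr,
#'   status.
#' @export
classify_degs <- function(table, cfg = pipeline_config()) {
  if (!"fdr" %in% names(table)) {
    if (!"p_value" %in% names(table)) stop("need fdr or p_value column")
    table$fdr <- bh_fdr(table$p_value)
  }
  passes <- 2^abs(table$log2fc) >= cfg$deg_fc_min &
    table$fdr < cfg$deg_fdr_max
  table$status <- ifelse(!passes, "ns",
                         ifelse(table$log2fc < 0, "down", "up"))
  rownames(table) <- NULL
  table
}

#' Two-time-point DEG summary arithmetic
#'
#' Reports, per time point, DEG counts, the up/down split with
#' round-half-up integer percentages, and the DEG share of the genome;
#' across time points, the shared DEG count and its percentage of each DEG
#' set. Percentages of an empty DEG set are NA, not 0.
#'
#' @param degs_t1,degs_t2 classified DEG tables (see [classify_degs()]).
#' @param genome_size number of annotated genes (e.g. ~7200 for a
#'   Streptomyces chromosome).
#' @return list of summary fields.
#' @export
deg_summary <- function(degs_t1, degs_t2, genome_size) {
  one <- function(d) {
    deg <- d[d$status != "ns", ]
    list(n_deg = nrow(deg),
         n_down = sum(deg$status == "down"),
         n_up = sum(deg$status == "up"),
         pct_down = pct_int(sum(deg$status == "down"), nrow(deg)),
         pct_up = pct_int(sum(deg$status == "up"), nrow(deg)),
         pct_of_genome = pct_int(nrow(deg), genome_size),
         tags = deg$locus_tag)
  }
  s1 <- one(degs_t1)
  s2 <- one(degs_t2)
  shared <- intersect(s1$tags, s2$tags)
  list(
    t1 = s1[setdiff(names(s1), "tags")],
    t2 = s2[setdiff(names(s2), "tags")],
    n_shared = length(shared),
    pct_shared_t1 = pct_int(length(shared), s1$n_deg),
    pct_shared_t2 = pct_int(length(shared), s2$n_deg)
  )
}
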