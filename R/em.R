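#' EM motif discovery over sequence fragments
#'
#' A deliberately small re-implementation of "any number of repetitions"
#' style motif discovery: every window of the requested width (both strands)
#' is modelled as a draw from a two-component mixture of a motif PWM and an
#' order-0 background, with mixing weight gamma shared across windows. The
#' E-step computes each window's motif posterior from the motif-vs-background
#' odds; the M-step re-estimates the PWM from posterior-weighted counts
#' (with a small Dirichlet pseudocount, so the maximized objective is the
#' penalized log-likelihood, which is non-decreasing across iterations) and
#' gamma from the mean posterior. The best restart by final objective wins.
#'
#' @param seqs character vector of A/C/G/T/N sequences, each at least
#'   `width` long (shorter ones are dropped; all shorter is an error).
#' @param width motif width.
#' @param restarts number of random restarts (>= 1).
#' @param seed RNG seed; the run is a pure function of it.
#' @param max_iter iteration cap per restart.
#' @param tol stop when the objective gain drops below this.
#' @param pseudo total Dirichlet pseudocount per column, spread by
#'   background.
#' @return list with `pwm` (the discovered [pwm()]), `sites` (data.frame of
#'   windows with posterior > 0.5: seq, start 0-based, strand, posterior,
#'   site sequence on the motif strand), `gamma`, `loglik` (objective trace
#'   of the winning restart), `background`.
#' @export
em_discover <- function(seqs, width, restarts = 8L, seed = 1L,
                        max_iter = 200L, tol = 1e-6, pseudo = 1) {
  seqs <- toupper(seqs)
  keep <- nchar(seqs) >= width
  if (!any(keep)) stop("all sequences shorter than motif width")
  seqs <- seqs[keep]
  if (restarts < 1) stop("restarts must be >= 1")

  # forward-strand window matrix, N-containing windows dropped; the minus
  # strand enters as a latent orientation within each window (a physical
  # site is one window, not two), which prevents EM from "palindromizing"
  # by merging the two orientations of the same planted word
  enc <- lapply(seqs, encode_dna)
  win <- list(); meta <- list()
  for (i in seq_along(enc)) {
    e <- enc[[i]]
    n_win <- length(e) - width + 1L
    idx <- outer(seq_len(n_win), 0:(width - 1L), `+`)
    m <- matrix(e[idx], n_win, width)
    ok <- !apply(is.na(m), 1, any)
    if (any(ok)) {
      win[[length(win) + 1L]] <- m[ok, , drop = FALSE]
      meta[[length(meta) + 1L]] <- data.frame(seq = i, start = which(ok) - 1L)
    }
  }
  W <- do.call(rbind, win)
  Wrc <- (5L - W)[, width:1, drop = FALSE]
  meta <- do.call(rbind, meta)
  n <- nrow(W)
  if (n == 0) stop("no scannable windows")

  base_freq <- tabulate(unlist(enc), nbins = 4)
  bg <- base_freq / sum(base_freq)
  logbg <- log(bg)
  lb <- numeric(n)
  for (j in seq_len(width)) lb <- lb + logbg[W[, j]]

  run_em <- function(probs0, gamma0) {
    probs <- probs0
    gamma <- gamma0
    ll_trace <- numeric(0)
    prior <- pseudo * bg
    penalty <- function(p) sum(prior * log(p))
    ll_old <- -Inf
    z <- zf <- zr <- NULL
    for (it in seq_len(max_iter)) {
      lp <- log(probs)
      lprc <- lp[4:1, width:1, drop = FALSE]
      lm_f <- lm_r <- numeric(n)
      for (j in seq_len(width)) {
        lm_f <- lm_f + lp[W[, j], j]
        lm_r <- lm_r + lprc[W[, j], j]   # rc(window) scored under the PWM
      }
      mo <- pmax(lm_f, lm_r)
      lm <- mo + log(0.5 * exp(lm_f - mo) + 0.5 * exp(lm_r - mo))
      a <- log(gamma) + lm
      b <- log1p(-gamma) + lb
      mx <- pmax(a, b)
      ll <- sum(mx + log(exp(a - mx) + exp(b - mx))) +
        sum(apply(probs, 2, penalty))
      ll_trace <- c(ll_trace, ll)
      if (ll < ll_old - 1e-6) stop("internal: EM objective decreased")
      z <- 1 / (1 + exp(b - a))
      wf <- 1 / (1 + exp(lm_r - lm_f))   # orientation posterior
      zf <- z * wf
      zr <- z * (1 - wf)
      if (ll - ll_old < tol) break
      ll_old <- ll
      counts <- matrix(0, 4, width)
      for (j in seq_len(width)) {
        for (bse in 1:4) {
          counts[bse, j] <- sum(zf[W[, j] == bse]) + sum(zr[Wrc[, j] == bse])
        }
      }
      probs <- sweep(counts + prior, 2, colSums(counts) + pseudo, `/`)
      gamma <- min(0.5, max(1e-6, mean(z)))
    }
    list(probs = probs, gamma = gamma, z = z, zf = zf, zr = zr,
         loglik = ll_trace)
  }

  # phase-shift refinement: EM over overlapping windows is prone to locking
  # onto the true motif displaced by a column or two; restarting from the
  # converged PWM shifted left/right (vacated columns reset to background)
  # lets the higher-likelihood unshifted phase win
  shift_probs <- function(probs, s) {
    out <- matrix(rep(bg, width), 4, width)
    if (s > 0) out[, (s + 1):width] <- probs[, 1:(width - s)]
    else out[, 1:(width + s)] <- probs[, (1 - s):width]
    out
  }
  final_ll <- function(fit) utils::tail(fit$loglik, 1)

  set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    seed_win <- W[sample.int(n, 1L), ]
    probs0 <- matrix(rep(bg, width) * 0.45, 4, width)
    probs0[cbind(seed_win, seq_len(width))] <-
      probs0[cbind(seed_win, seq_len(width))] + 0.55
    probs0 <- sweep(probs0, 2, colSums(probs0), `/`)
    fit <- run_em(probs0, gamma0 = length(seqs) / n)
    for (round in 1:4) {
      improved <- FALSE
      for (s in c(-1L, 1L)) {
        alt <- run_em(shift_probs(fit$probs, s), gamma0 = fit$gamma)
        if (final_ll(alt) > final_ll(fit) + 1e-6) {
          fit <- alt
          improved <- TRUE
        }
      }
      if (!improved) break
    }
    if (is.null(best) || final_ll(fit) > final_ll(best)) {
      best <- fit
    }
  }

  site_idx <- which(best$z > 0.5)
  sites <- meta[site_idx, , drop = FALSE]
  sites$strand <- ifelse(best$zf[site_idx] >= best$zr[site_idx], "+", "-")
  sites$posterior <- best$z[site_idx]
  sites$site <- vapply(seq_along(site_idx), function(k) {
    i <- site_idx[k]
    decode_dna(if (sites$strand[k] == "+") W[i, ] else Wrc[i, ])
  }, character(1))
  sites <- sites[order(sites$seq, sites$start, sites$strand), ]
  rownames(sites) <- NULL
  out_pwm <- pwm(best$probs, background = bg, pseudocount = pseudo,
                 n_sites = length(site_idx))
  list(pwm = out_pwm, sites = sites, gamma = best$gamma,
       loglik = best$loglik, background = bg)
}
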