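# AKV probability distributions and non-parametric comparisons.

# Standard bin geometry: a dedicated origin bin [0, zero_bin_edge) that
# accumulates pauses and perfectly stable articulation, then n_bins - 1
# uniform bins up to v_max. Feature dimension equals n_bins.
akv_bin_edges <- function(n_bins = 50, v_max = 25, zero_bin_edge = 0.05) {
  if (v_max <= zero_bin_edge) stop_input("v_max must exceed zero_bin_edge")
  c(0, seq(zero_bin_edge, v_max, length.out = n_bins))
}

#' AKV distribution from a velocity series
#'
#' Normalised histogram of absolute kinematic velocity values — the
#' non-parametric descriptor of a segment's articulation kinematics. The
#' first bin is the origin bin (region R1); values above `v_max` are
#' clipped into the last bin.
#'
#' @param akv Numeric vector of AKV values (cm/s), non-negative.
#' @param n_bins Total number of bins (= feature dimension).
#' @param v_max Histogram upper edge (cm/s).
#' @param zero_bin_edge Upper edge of the origin bin (cm/s).
#' @return Object of class `akv_distribution`: `bin_edges`, `p` (sums to
#'   1), `n_samples`.
#' @export
akv_histogram <- function(akv, n_bins = 50, v_max = 25, zero_bin_edge = 0.05) {
  if (length(akv) == 0L) stop_input("empty AKV series")
  if (!all(is.finite(akv))) stop_input("AKV series must be finite")
  if (any(akv < 0)) stop_input("AKV values must be non-negative")
  edges <- akv_bin_edges(n_bins, v_max, zero_bin_edge)
  v <- pmin(akv, v_max)
  counts <- tabulate(findInterval(v, edges, rightmost.closed = TRUE),
                     nbins = n_bins)
  structure(list(bin_edges = edges, p = counts / sum(counts),
                 n_samples = length(akv)),
            class = "akv_distribution")
}

#' @export
print.akv_distribution <- function(x, ...) {
  r <- region_masses(x)
  cat(sprintf(
    "akv_distribution: %d bins over [0, %g] cm/s, n = %d\n  R1 %.3f | R2 %.3f | R3 %.3f | R4 %.3f\n",
    length(x$p), max(x$bin_edges), x$n_samples, r$R1, r$R2, r$R3, r$R4))
  invisible(x)
}

#' Region masses R1-R4
#'
#' Probability mass of the four interpretive zones of the AKV
#' distribution: R1 the origin bin (pauses and silent intervals), R2 the
#' remainder below 3 cm/s (stable vowel nuclei), R3 between 3 and 10 cm/s
#' (smooth glide-like adjustments, centred around 5 cm/s), R4 above
#' 10 cm/s (sharp articulation onsets). Bins straddling a region boundary
#' are split proportionally.
#'
#' @param d An `akv_distribution`.
#' @return Object of class `region_masses` with fields R1..R4 summing to 1.
#' @export
region_masses <- function(d) {
  stopifnot(inherits(d, "akv_distribution"))
  edges <- d$bin_edges
  if (max(edges) < 10) stop_input("v_max < 10 cm/s: region R4 undefined")
  mass_in <- function(lo, hi) {
    l <- edges[-length(edges)]
    u <- edges[-1]
    width <- pmax(u - l, .Machine$double.eps)
    overlap <- pmax(0, pmin(u, hi) - pmax(l, lo))
    sum(d$p * overlap / width)
  }
  r1 <- d$p[1]
  r2 <- mass_in(edges[2], 3)
  r3 <- mass_in(3, 10)
  r4 <- mass_in(10, max(edges))
  structure(list(R1 = r1, R2 = r2, R3 = r3, R4 = r4),
            class = "region_masses")
}

#' Kullback-Leibler divergence between AKV distributions
#'
#' \eqn{D(p\|q) = \sum_i p_i \log(p_i/q_i)} in nats, after adding `eps` to
#' both mass vectors and renormalising (keeps the divergence finite on
#' sparse histograms). Asymmetric; zero iff the smoothed distributions
#' coincide.
#'
#' @param p,q `akv_distribution` objects (or bare probability vectors) on
#'   identical bin geometry.
#' @param eps Smoothing constant added to every bin.
#' @return Divergence in nats (non-negative).
#' @export
kld <- function(p, q, eps = 1e-8) {
  pv <- if (inherits(p, "akv_distribution")) p$p else as.numeric(p)
  qv <- if (inherits(q, "akv_distribution")) q$p else as.numeric(q)
  if (inherits(p, "akv_distribution") && inherits(q, "akv_distribution") &&
      !isTRUE(all.equal(p$bin_edges, q$bin_edges))) {
    stop_input("distributions must share bin geometry")
  }
  if (length(pv) != length(qv)) stop_input("mass vectors must have equal length")
  ps <- (pv + eps) / sum(pv + eps)
  qs <- (qv + eps) / sum(qv + eps)
  if (eps == 0) {
    keep <- ps > 0
    if (any(qs[keep] == 0)) return(Inf)
    return(sum(ps[keep] * log(ps[keep] / qs[keep])))
  }
  sum(ps * log(ps / qs))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Supremum distance between empirical CDFs with asymptotic (or, for
#' small samples without ties, exact) p-value.
#'
#' @param a,b Numeric samples.
#' @return List with `statistic` and `p_value`.
#' @export
ks_two_sample <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop_input("samples must be non-empty")
  if (length(a) < 5L || length(b) < 5L) {
    warning("n < 5: asymptotic KS p-value unreliable")
  }
  res <- suppressWarnings(stats::ks.test(a, b))
  list(statistic = unname(res$statistic), p_value = res$p.value)
}

#' Lilliefors normality test
#'
#' Kolmogorov-Smirnov test against a normal with mean and SD estimated
#' from the sample, with the Lilliefors small-sample correction of the
#' p-value. Constant samples are degenerate and rejected outright.
#'
#' @param a Numeric sample, n >= 5.
#' @return p-value.
#' @export
lilliefors_normality <- function(a) {
  if (length(a) < 5L) stop_input("need n >= 5 for the Lilliefors test")
  if (stats::sd(a) == 0) return(1e-4)  # degenerate: reject
  nortest::lillie.test(a)$p.value
}

#' Wilcoxon-Mann-Whitney rank-sum test
#'
#' Two-sided rank-sum test with tie correction; exact enumeration for
#' small tie-free samples.
#'
#' @param a,b Numeric samples.
#' @return p-value.
#' @export
wilcoxon_rank_sum <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop_input("samples must be non-empty")
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1L) return(1)
  suppressWarnings(stats::wilcox.test(a, b, exact = NULL)$p.value)
}

#' Pairwise KS failure rate between cohorts
#'
#' Runs a two-sample KS test for every (target, model) pair of subjects —
#' e.g. 53 pathological x 26 normative = 1,378 tests — on their raw AKV
#' draws, and reports the percentage of pairs where the test fails to
#' reject at `alpha`, i.e. the percentage of pathological subjects
#' indistinguishable from normative ones.
#'
#' @param targets,models Lists of numeric AKV sample vectors (one per
#'   subject).
#' @param alpha Significance level.
#' @return List with `failure_pct`, `n_tests`, `n_failures`.
#' @export
pairwise_ks_failure_rate <- function(targets, models, alpha = 0.05) {
  if (length(targets) < 1L || length(models) < 1L) {
    stop_input("need at least one subject per side")
  }
  n_fail <- 0L
  n_tests <- 0L
  for (tg in targets) {
    for (md in models) {
      p <- suppressWarnings(stats::ks.test(tg, md)$p.value)
      n_tests <- n_tests + 1L
      if (p >= alpha) n_fail <- n_fail + 1L
    }
  }
  list(failure_pct = 100 * n_fail / n_tests, n_tests = n_tests,
       n_failures = n_fail)
}
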