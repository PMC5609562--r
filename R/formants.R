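#' Formant track container
#'
#' Time series of the first two formant frequencies on a uniform frame
#' grid, with a per-frame validity flag (frames of silence or with too few
#' resonance candidates are invalid).
#'
#' @param t Frame times (s), uniform hop.
#' @param f1,f2 First / second formant (Hz); `NA` allowed on invalid
#'   frames.
#' @param valid Logical per-frame flag.
#' @return Object of class `formant_track`.
#' @export
formant_track <- function(t, f1, f2, valid = rep(TRUE, length(t))) {
  n <- length(t)
  if (length(f1) != n || length(f2) != n || length(valid) != n) {
    stop_input("t, f1, f2, valid must have equal length")
  }
  if (n >= 3) {
    hops <- diff(t)
    if (max(hops) - min(hops) > 1e-9) stop_input("frame hop must be uniform")
  }
  bad <- valid & (!is.finite(f1) | !is.finite(f2) | f1 <= 0 | f1 >= f2)
  if (any(bad)) stop_input("valid frames must satisfy 0 < f1 < f2 and be finite")
  structure(list(t = as.numeric(t), f1 = as.numeric(f1), f2 = as.numeric(f2),
                 valid = as.logical(valid)),
            class = "formant_track")
}

#' @export
print.formant_track <- function(x, ...) {
  cat(sprintf(
    "formant_track: %d frames, hop %.3g ms, %.0f%% valid; median F1 = %.0f Hz, F2 = %.0f Hz\n",
    length(x$t), 1000 * (if (length(x$t) > 1) x$t[2] - x$t[1] else NA),
    100 * mean(x$valid),
    stats::median(x$f1[x$valid]), stats::median(x$f2[x$valid])))
  invisible(x)
}

#' Per-frame linear-prediction analysis
#'
#' Slides a Hamming window over the segment and fits an autocorrelation
#' LPC polynomial of the given order per frame (block LPC at 2 ms hop in
#' place of an adaptive lattice-ladder of the same order — an equivalent
#' spectral estimator for stationary vowel frames). Polynomials are
#' stabilised by reflecting any pole outside the unit circle. Frames whose
#' energy falls below `energy_floor` times the segment's median frame
#' energy carry no polynomial and are flagged invalid.
#'
#' @param seg A preprocessed [speech_segment()] at the working rate.
#' @param order LPC order (default 9).
#' @param hop_ms,win_ms Frame hop and window length (ms).
#' @param energy_floor Relative energy threshold for voicing.
#' @return A list with `t` (frame centre times), `coef` (list of
#'   `a`-polynomials, `NULL` where invalid), `valid`, and `fs`.
#' @export
lpc_frames <- function(seg, order = 9, hop_ms = 2, win_ms = 25,
                       energy_floor = 1e-4) {
  stopifnot(inherits(seg, "speech_segment"))
  fs <- seg$fs
  x <- seg$samples
  n_win <- round(win_ms / 1000 * fs)
  n_hop <- round(hop_ms / 1000 * fs)
  if (length(x) < n_win) stop_input("segment shorter than one analysis window")
  starts <- seq(1, length(x) - n_win + 1, by = n_hop)
  w <- 0.54 - 0.46 * cos(2 * pi * seq(0, n_win - 1) / (n_win - 1))
  energies <- vapply(starts, function(s) mean(x[s:(s + n_win - 1)]^2), 0)
  floor_e <- energy_floor * stats::median(energies)
  coefs <- vector("list", length(starts))
  valid <- logical(length(starts))
  for (i in seq_along(starts)) {
    if (energies[i] <= floor_e) next
    fr <- x[starts[i]:(starts[i] + n_win - 1)] * w
    a <- lpc_autocor(fr, order)
    if (is.null(a)) next
    coefs[[i]] <- stabilize_lpc(a)
    valid[i] <- TRUE
  }
  list(t = (starts - 1 + n_win / 2) / fs, coef = coefs, valid = valid, fs = fs)
}

# Autocorrelation-method LPC via Levinson-Durbin; returns c(1, -a1..-ap)
# such that A(z) = 1 - sum a_k z^-k, or NULL for a degenerate frame.
lpc_autocor <- function(frame, order) {
  n <- length(frame)
  r <- vapply(0:order, function(k) sum(frame[1:(n - k)] * frame[(1 + k):n]), 0)
  if (r[1] <= 0) return(NULL)
  r[1] <- r[1] * (1 + 1e-9)  # tiny ridge guards against singular frames
  a <- numeric(order)
  e <- r[1]
  for (i in seq_len(order)) {
    acc <- r[i + 1]
    if (i > 1) acc <- acc - sum(a[1:(i - 1)] * r[i:2])
    k <- acc / e
    a_new <- a
    a_new[i] <- k
    if (i > 1) a_new[1:(i - 1)] <- a[1:(i - 1)] - k * a[(i - 1):1]
    a <- a_new
    e <- e * (1 - k^2)
    if (e <= 0) return(NULL)
  }
  c(1, -a)
}

# Reflect poles with |z| > 1 inside the unit circle (same magnitude
# response).
stabilize_lpc <- function(a) {
  z <- polyroot(rev(a))
  out <- abs(z) > 1
  if (!any(out)) return(a)
  z[out] <- 1 / Conj(z[out])
  coef <- 1
  for (zi in z) coef <- c(coef, 0) - c(0, coef) * zi
  Re(rev(coef) / coef[1])[seq_along(a)]
}

#' Pick formants from LPC frames
#'
#' Converts each frame's prediction polynomial into resonance candidates
#' (complex-pole angles whose equivalent bandwidth is below
#' `bw_max` and whose frequency exceeds `f_floor`, rejecting glottal and
#' rounding poles), then assigns F1/F2 per frame. When more than two
#' candidates are present the pair closest to the previous frame's
#' assignment is kept (continuity constraint); otherwise the two lowest
#' candidates. Frames with fewer than two candidates are invalid.
#'
#' @param frames Output of [lpc_frames()].
#' @param fs Sampling rate (Hz); defaults to the rate stored in `frames`.
#' @param bw_max Maximum pole bandwidth (Hz) for formant candidacy.
#' @param f_floor Minimum candidate frequency (Hz).
#' @return A [formant_track()].
#' @export
pick_formants <- function(frames, fs = frames$fs, bw_max = 400, f_floor = 150) {
  n <- length(frames$t)
  f1 <- rep(NA_real_, n)
  f2 <- rep(NA_real_, n)
  valid <- logical(n)
  prev <- NULL
  for (i in seq_len(n)) {
    if (!frames$valid[i]) next
    z <- polyroot(rev(frames$coef[[i]]))
    z <- z[Im(z) > 1e-6]
    freq <- Arg(z) * fs / (2 * pi)
    bw <- -log(pmin(abs(z), 1 - 1e-12)) * fs / pi
    keep <- bw < bw_max & freq > f_floor & freq < fs / 2 - 50
    cand <- sort(freq[keep])
    if (length(cand) < 2L) next
    if (length(cand) > 2L && !is.null(prev)) {
      pairs <- utils::combn(cand, 2)
      cost <- abs(pairs[1, ] - prev[1]) + abs(pairs[2, ] - prev[2])
      pick <- pairs[, which.min(cost)]
    } else {
      pick <- cand[1:2]
    }
    f1[i] <- min(pick)
    f2[i] <- max(pick)
    valid[i] <- TRUE
    prev <- c(f1[i], f2[i])
  }
  formant_track(frames$t, f1, f2, valid)
}

#' Smooth a formant track
#'
#' Glitch removal for formant trajectories: isolated single-frame jumps
#' larger than `spike_hz` are replaced by the neighbour mean, short
#' invalid gaps (below `max_gap_ms`) are linearly interpolated, then a
#' 3-point running median and a zero-phase 2nd-order low-pass smoother
#' are applied. The smoother cut-off (default 50 Hz at a 500 Hz frame
#' rate) is set well above the 20 Hz kinematic band so that pathological
#' tremor is transmitted essentially unattenuated.
#'
#' @param track A [formant_track()].
#' @param spike_hz Single-frame jump magnitude treated as a glitch.
#' @param max_gap_ms Longest invalid gap (ms) to interpolate across.
#' @param smooth_cutoff_hz Cut-off of the final low-pass smoother (Hz).
#' @return A smoothed [formant_track()], valid everywhere the input gaps
#'   allowed.
#' @export
smooth_formants <- function(track, spike_hz = 300, max_gap_ms = 10,
                            smooth_cutoff_hz = 50) {
  stopifnot(inherits(track, "formant_track"))
  if (mean(track$valid) < 0.5) {
    stop_input("fewer than 50% valid frames: track quality too poor to smooth")
  }
  hop <- track$t[2] - track$t[1]
  frame_rate <- 1 / hop
  clean1 <- function(f, valid) {
    f[!valid] <- NA
    # fill short gaps
    idx <- seq_along(f)
    ok <- !is.na(f)
    gaps <- rle(ok)
    pos <- cumsum(c(1, gaps$lengths))
    for (g in which(!gaps$values)) {
      len <- gaps$lengths[g]
      if (len * hop * 1000 <= max_gap_ms && g > 1 && g < length(gaps$values)) {
        span <- pos[g]:(pos[g + 1] - 1)
        f[span] <- stats::approx(idx[ok], f[ok], span, rule = 2)$y
      }
    }
    ok <- !is.na(f)
    # isolated spikes
    for (i in which(ok)[-c(1, sum(ok))]) {
      j <- which(ok)
      k <- match(i, j)
      lo <- j[k - 1]; hi <- j[k + 1]
      nb <- (f[lo] + f[hi]) / 2
      if (abs(f[i] - nb) > spike_hz &&
          abs(f[hi] - f[lo]) < spike_hz) {
        f[i] <- nb
      }
    }
    f
  }
  f1 <- clean1(track$f1, track$valid)
  f2 <- clean1(track$f2, track$valid)
  valid <- !is.na(f1) & !is.na(f2)
  smooth1 <- function(f) {
    v <- !is.na(f)
    y <- f[v]
    if (length(y) >= 7) {
      y <- stats::runmed(y, 3)
      wc <- min(smooth_cutoff_hz, 0.45 * frame_rate / 2 * 2) / (frame_rate / 2)
      if (wc < 1) {
        b <- signal::butter(2, wc)
        # pad by reflection to tame filtfilt end transients on short tracks
        np <- min(length(y) - 1, 50)
        yp <- c(2 * y[1] - y[(np + 1):2], y, 2 * y[length(y)] - y[(length(y) - 1):(length(y) - np)])
        yf <- signal::filtfilt(b, yp)
        y <- yf[(np + 1):(np + length(y))]
      }
    }
    f[v] <- y
    f
  }
  formant_track(track$t, smooth1(f1), smooth1(f2), valid)
}

#' Track formants of a preprocessed vowel
#'
#' Convenience chain: [lpc_frames()] then [pick_formants()] then
#' [smooth_formants()].
#'
#' @param seg A preprocessed [speech_segment()].
#' @param cfg An [akv_config()].
#' @return A smoothed [formant_track()].
#' @export
track_formants <- function(seg, cfg = akv_config()) {
  fr <- lpc_frames(seg, order = cfg$lpc_order, hop_ms = cfg$frame_hop_ms,
                   win_ms = cfg$win_ms)
  smooth_formants(pick_formants(fr))
}

#' Export a formant track to CSV
#'
#' @param track A [formant_track()].
#' @param path Output CSV path (columns t, f1, f2, valid).
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path) {
  utils::write.csv(data.frame(t = track$t, f1 = track$f1, f2 = track$f2,
                              valid = track$valid),
                   path, row.names = FALSE)
  invisible(path)
}
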