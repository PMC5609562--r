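#' Jaw-tongue calibration weights
#'
#' Scales mapping formant derivatives onto reference-point velocities:
#' `w12` maps \eqn{df_2/dt} to the horizontal (rostral-caudal) velocity
#' and `w21` maps \eqn{df_1/dt} to the vertical (dorsal-ventral) velocity,
#' both in cm s. The diagonal terms of the full articulatory-to-formant
#' sensitivity matrix are negligible against these and are not modelled.
#' Defaults are the male-speaker diphthong calibration values.
#'
#' @param w12,w21 Positive scales in cm s.
#' @return Object of class `calibration_weights`.
#' @export
calibration_weights <- function(w12 = 1.62e-3, w21 = 1.47e-3) {
  assert_scalar_pos(w12, "w12")
  assert_scalar_pos(w21, "w21")
  structure(list(w12 = w12, w21 = w21), class = "calibration_weights")
}

#' Formant time derivatives
#'
#' Central differences on the uniform frame grid,
#' \eqn{(df/dt)[k] = (f[k+1]-f[k-1])/2h}, one-sided at the ends; exact for
#' linear trajectories and half the high-frequency noise amplification of
#' first differences. Only the longest contiguous run of valid frames is
#' differentiated.
#'
#' @param track A smoothed [formant_track()].
#' @return List with `t`, `df1dt`, `df2dt` (Hz/s) and `hop` (s).
#' @export
formant_derivatives <- function(track) {
  stopifnot(inherits(track, "formant_track"))
  run <- longest_valid_run(track$valid)
  if (length(run) < 3) stop_input("need at least 3 valid frames")
  t <- track$t[run]
  h <- t[2] - t[1]
  d <- function(f) {
    n <- length(f)
    c(f[2] - f[1], (f[3:n] - f[1:(n - 2)]) / 2, f[n] - f[n - 1]) / h
  }
  list(t = t, df1dt = d(track$f1[run]), df2dt = d(track$f2[run]), hop = h)
}

longest_valid_run <- function(valid) {
  r <- rle(valid)
  ends <- cumsum(r$lengths)
  ok <- which(r$values)
  if (length(ok) == 0L) return(integer(0))
  best <- ok[which.max(r$lengths[ok])]
  (ends[best] - r$lengths[best] + 1):ends[best]
}

#' Low-pass filter formant derivatives
#'
#' Zero-phase (forward-backward) 4th-order Butterworth low-pass with unit
#' DC gain. Articulator inertia makes formant-derivative content above
#' about 20 Hz physiologically implausible, so it is removed before the
#' velocity computation.
#'
#' @param deriv Output of [formant_derivatives()].
#' @param cutoff_hz Cut-off frequency (Hz), default 20.
#' @return `deriv` with `df1dt`/`df2dt` filtered.
#' @export
lowpass_derivatives <- function(deriv, cutoff_hz = 20) {
  frame_rate <- 1 / deriv$hop
  if (cutoff_hz >= frame_rate / 2) {
    stop_input("cutoff must be below the frame-rate Nyquist (",
               frame_rate / 2, " Hz)")
  }
  b <- signal::butter(4, cutoff_hz / (frame_rate / 2))
  lp <- function(x) {
    np <- min(length(x) - 1, ceiling(10 * frame_rate / cutoff_hz))
    xp <- c(2 * x[1] - x[(np + 1):2], x,
            2 * x[length(x)] - x[(length(x) - 1):(length(x) - np)])
    y <- signal::filtfilt(b, xp)
    y[(np + 1):(np + length(x))]
  }
  deriv$df1dt <- lp(deriv$df1dt)
  deriv$df2dt <- lp(deriv$df2dt)
  deriv
}

#' Absolute kinematic velocity series
#'
#' Maps filtered formant derivatives to reference-point velocities,
#' \eqn{v_x = w_{12}\,df_2/dt}, \eqn{v_y = w_{21}\,df_1/dt}, and their
#' magnitude, the absolute kinematic velocity
#' \eqn{|v| = \sqrt{v_x^2 + v_y^2}} in cm/s.
#'
#' @param deriv Output of [lowpass_derivatives()] (or raw derivatives).
#' @param w A [calibration_weights()].
#' @return Object of class `kinematic_track` with `t`, `vx`, `vy`, `akv`.
#' @export
akv_series <- function(deriv, w = calibration_weights()) {
  stopifnot(inherits(w, "calibration_weights"))
  if (length(deriv$df1dt) != length(deriv$df2dt)) {
    stop_input("derivative series must have equal length")
  }
  vx <- w$w12 * deriv$df2dt
  vy <- w$w21 * deriv$df1dt
  structure(list(t = deriv$t, vx = vx, vy = vy, akv = sqrt(vx^2 + vy^2)),
            class = "kinematic_track")
}

#' @export
print.kinematic_track <- function(x, ...) {
  cat(sprintf("kinematic_track: %d frames, median AKV %.2f cm/s, max %.2f cm/s\n",
              length(x$akv), stats::median(x$akv), max(x$akv)))
  invisible(x)
}

#' Full kinematic chain from a formant track
#'
#' Derivatives, 20 Hz zero-phase low-pass, then AKV.
#'
#' @param track A smoothed [formant_track()].
#' @param cfg An [akv_config()].
#' @return A `kinematic_track`.
#' @export
akv_from_track <- function(track, cfg = akv_config()) {
  d <- lowpass_derivatives(formant_derivatives(track),
                           cutoff_hz = cfg$lowpass_cutoff_hz)
  akv_series(d, calibration_weights(cfg$w12, cfg$w21))
}

#' End-to-end AKV distribution from audio
#'
#' Preprocess, track formants, compute AKV, histogram: the complete
#' per-subject feature extraction.
#'
#' @param seg A [speech_segment()] (any rate; resampled internally).
#' @param cfg An [akv_config()].
#' @return An `akv_distribution` (see [akv_histogram()]).
#' @export
akv_pipeline <- function(seg, cfg = akv_config()) {
  pre <- preprocess(seg, cfg)
  kin <- akv_from_track(track_formants(pre, cfg), cfg)
  akv_histogram(kin$akv, cfg$n_bins, cfg$v_max, cfg$zero_bin_edge)
}
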