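#' Pipeline configuration
#'
#' Bundles every tunable setting of the vowel-kinematics pipeline into one
#' validated list. Defaults follow the analysis protocol the package
#' implements: sustained vowels down-sampled to 8 kHz, 500 ms analysis
#' segments, 9th-order linear prediction evaluated every 2 ms, formant
#' derivatives low-pass filtered at 20 Hz, and the jaw-tongue calibration
#' scales \eqn{w_{12} = 1.62\times10^{-3}} and
#' \eqn{w_{21} = 1.47\times10^{-3}} cm s (male-speaker diphthong
#' calibration).
#'
#' @param target_fs Working sampling rate in Hz after resampling.
#' @param segment_ms Analysis segment length in milliseconds.
#' @param lpc_order Linear-prediction order for vocal-tract inversion.
#' @param frame_hop_ms Analysis hop between LPC frames in milliseconds.
#' @param win_ms LPC analysis window length in milliseconds.
#' @param lowpass_cutoff_hz Cut-off (Hz) of the zero-phase low-pass applied
#'   to formant derivatives; articulator inertia makes content above
#'   ~20 Hz uninformative.
#' @param w12,w21 Calibration scales (cm s) mapping \eqn{df_2/dt} to the
#'   horizontal and \eqn{df_1/dt} to the vertical reference-point velocity.
#' @param n_bins Number of histogram bins of the AKV distribution (the
#'   feature dimension); the first bin is the dedicated zero/origin bin.
#' @param v_max Upper edge (cm/s) of the AKV histogram; faster values are
#'   clipped into the last bin.
#' @param zero_bin_edge Upper edge (cm/s) of the origin bin collecting
#'   near-zero velocities (pauses / perfectly stable articulation).
#' @param n_hidden Hidden-layer width of the random least-squares network.
#' @param n_mc_epochs Number of Monte Carlo epochs for stability analysis.
#' @param deemph_alpha First-order de-emphasis coefficient used as lip
#'   radiation compensation before LPC.
#' @param master_seed Integer seed from which all derived seeds are hashed.
#'
#' @return An object of class `akv_config` (a named list).
#' @examples
#' cfg <- akv_config()
#' cfg$lpc_order
#' @export
akv_config <- function(target_fs = 8000,
                       segment_ms = 500,
                       lpc_order = 9,
                       frame_hop_ms = 2,
                       win_ms = 25,
                       lowpass_cutoff_hz = 20,
                       w12 = 1.62e-3,
                       w21 = 1.47e-3,
                       n_bins = 50,
                       v_max = 25,
                       zero_bin_edge = 0.05,
                       n_hidden = 200,
                       n_mc_epochs = 200,
                       deemph_alpha = 0.95,
                       master_seed = 1L) {
  cfg <- list(
    target_fs = target_fs, segment_ms = segment_ms, lpc_order = lpc_order,
    frame_hop_ms = frame_hop_ms, win_ms = win_ms,
    lowpass_cutoff_hz = lowpass_cutoff_hz, w12 = w12, w21 = w21,
    n_bins = n_bins, v_max = v_max, zero_bin_edge = zero_bin_edge,
    n_hidden = n_hidden, n_mc_epochs = n_mc_epochs,
    deemph_alpha = deemph_alpha, master_seed = as.integer(master_seed)
  )
  for (nm in c("target_fs", "segment_ms", "lpc_order", "frame_hop_ms",
               "win_ms", "lowpass_cutoff_hz", "w12", "w21", "n_bins",
               "v_max", "zero_bin_edge")) {
    assert_scalar_pos(cfg[[nm]], nm)
  }
  if (cfg$n_hidden < 1) stop_input("`n_hidden` must be >= 1")
  if (cfg$n_bins < 4) stop_input("`n_bins` must be >= 4")
  structure(cfg, class = "akv_config")
}

#' @export
print.akv_config <- function(x, ...) {
  cat("AKV pipeline configuration\n")
  cat(sprintf("  audio: %g Hz, %g ms segments, de-emphasis %.2f\n",
              x$target_fs, x$segment_ms, x$deemph_alpha))
  cat(sprintf("  LPC: order %d, hop %g ms, window %g ms\n",
              x$lpc_order, x$frame_hop_ms, x$win_ms))
  cat(sprintf("  kinematics: w12 = %g, w21 = %g cm s; derivative LP %g Hz\n",
              x$w12, x$w21, x$lowpass_cutoff_hz))
  cat(sprintf("  histogram: %d bins over [0, %g] cm/s (zero bin < %g)\n",
              x$n_bins, x$v_max, x$zero_bin_edge))
  cat(sprintf("  classifier: %d hidden units, %d Monte Carlo epochs\n",
              x$n_hidden, x$n_mc_epochs))
  invisible(x)
}
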