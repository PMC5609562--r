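#' Tremor specification
#'
#' Parameterises the formant-frequency modulation imposed on a synthetic
#' sustained vowel. Pathological (hypokinetic) tremor lives in the 5-8 Hz
#' band with excursions of tens of Hz; physiological fine-tuning tremor
#' sits above 25 Hz with much smaller amplitude.
#'
#' @param band_hz Modulation frequency (Hz).
#' @param amp_f1_hz,amp_f2_hz Peak sinusoidal deviation of F1/F2 (Hz).
#' @param jitter_sd_hz SD of additive white frequency jitter (Hz).
#' @return Object of class `tremor_spec`.
#' @export
tremor_spec <- function(band_hz = 6, amp_f1_hz = 0, amp_f2_hz = 0,
                        jitter_sd_hz = 0) {
  assert_scalar_pos(band_hz, "band_hz")
  if (amp_f1_hz < 0 || amp_f2_hz < 0 || jitter_sd_hz < 0) {
    stop_input("tremor amplitudes must be >= 0")
  }
  structure(list(band_hz = band_hz, amp_f1_hz = amp_f1_hz,
                 amp_f2_hz = amp_f2_hz, jitter_sd_hz = jitter_sd_hz),
            class = "tremor_spec")
}

#' Pathological / physiological tremor presets
#'
#' Defaults used by the synthetic cohort: pathological tremor at 6 Hz
#' (centre of the 5-8 Hz band) with 50 Hz formant excursions; physiological
#' tremor at 30 Hz with 5 Hz excursions.
#'
#' @param class_label `"pathological"` or `"normative"`.
#' @return A [tremor_spec()].
#' @export
tremor_preset <- function(class_label = c("pathological", "normative")) {
  class_label <- match.arg(class_label)
  if (class_label == "pathological") {
    tremor_spec(band_hz = 6, amp_f1_hz = 50, amp_f2_hz = 70, jitter_sd_hz = 2)
  } else {
    tremor_spec(band_hz = 30, amp_f1_hz = 5, amp_f2_hz = 7, jitter_sd_hz = 2)
  }
}

#' Vowel specification
#'
#' Source-filter description of a synthetic sustained vowel: glottal
#' frequency, target formants and bandwidths, duration, rate and tremor.
#' Defaults approximate an open sustained a-vowel.
#'
#' @param f0 Glottal frequency (Hz).
#' @param formants Target formant frequencies (Hz), ascending.
#' @param bandwidths Formant bandwidths (Hz), same length as `formants`.
#' @param duration_s Duration (s).
#' @param fs Sampling rate (Hz).
#' @param tremor A [tremor_spec()].
#' @param seed Integer seed controlling jitter and phases.
#' @return Object of class `vowel_spec`.
#' @export
vowel_spec <- function(f0 = 110,
                       formants = c(700, 1200, 2600),
                       bandwidths = c(90, 110, 180),
                       duration_s = 0.5,
                       fs = 8000,
                       tremor = tremor_spec(),
                       seed = 1L) {
  assert_scalar_pos(f0, "f0")
  assert_scalar_pos(duration_s, "duration_s")
  assert_scalar_pos(fs, "fs")
  if (length(formants) < 2L || is.unsorted(formants, strictly = TRUE)) {
    stop_input("`formants` must be at least (F1, F2), strictly ascending")
  }
  if (any(formants >= fs / 2)) stop_input("formants must lie below Nyquist")
  if (f0 >= formants[1]) stop_input("f0 must be below F1 (unresolvable formant)")
  if (length(bandwidths) != length(formants)) {
    stop_input("`bandwidths` must match `formants` in length")
  }
  stopifnot(inherits(tremor, "tremor_spec"))
  structure(list(f0 = f0, formants = formants, bandwidths = bandwidths,
                 duration_s = duration_s, fs = fs, tremor = tremor,
                 seed = as.integer(seed)),
            class = "vowel_spec")
}

#' Synthesise a formant trajectory
#'
#' Generates the ground-truth F1/F2 trajectories of a vowel spec on a
#' uniform frame grid: target + sinusoidal tremor + white jitter,
#' deterministic given the spec seed.
#'
#' @param spec A [vowel_spec()].
#' @param hop_ms Frame hop in milliseconds.
#' @return A `formant_track` (see [formant_track()]).
#' @export
synth_formant_trajectory <- function(spec, hop_ms = 2) {
  stopifnot(inherits(spec, "vowel_spec"))
  hop <- hop_ms / 1000
  t <- seq(0, spec$duration_s - hop / 2, by = hop)
  tr <- spec$tremor
  with_seed(spec$seed, {
    phi <- stats::runif(2, 0, 2 * pi)
    f1 <- spec$formants[1] + tr$amp_f1_hz * sin(2 * pi * tr$band_hz * t + phi[1]) +
      stats::rnorm(length(t), 0, tr$jitter_sd_hz)
    f2 <- spec$formants[2] + tr$amp_f2_hz * sin(2 * pi * tr$band_hz * t + phi[2]) +
      stats::rnorm(length(t), 0, tr$jitter_sd_hz)
    if (any(f1 >= f2)) stop_input("tremor amplitudes cause F1/F2 crossing")
    formant_track(t, f1, f2, valid = rep(TRUE, length(t)))
  })
}

#' Synthesise a sustained vowel
#'
#' Passes a glottal pulse train at `f0` (with -6 dB/oct source shaping)
#' through a cascade of second-order resonators whose F1/F2 centre
#' frequencies follow the tremor-modulated trajectory, updated every
#' sample. Amplitude-normalised to peak 1. This is a test fixture in the
#' source-filter tradition, not a perceptual voice model.
#'
#' @param spec A [vowel_spec()].
#' @param label Cohort tag stored on the returned segment.
#' @return A list with elements `segment` (a [speech_segment()]) and
#'   `truth` (the ground-truth `formant_track`).
#' @export
synth_vowel <- function(spec, label = "unknown") {
  stopifnot(inherits(spec, "vowel_spec"))
  fs <- spec$fs
  n <- round(spec$duration_s * fs)
  truth <- synth_formant_trajectory(spec, hop_ms = 1000 / fs)
  f1 <- truth$f1[seq_len(n)]
  f2 <- truth$f2[seq_len(n)]

  # glottal source: impulse train + one-pole low-pass for spectral tilt
  src <- numeric(n)
  src[round(seq(1, n, by = fs / spec$f0))] <- 1
  src <- as.numeric(stats::filter(src, 0.95, method = "recursive"))

  y <- src
  n_res <- length(spec$formants)
  for (k in seq_len(n_res)) {
    fk <- switch(k, f1, f2, rep(spec$formants[k], n))
    r <- exp(-pi * spec$bandwidths[k] / fs)
    theta <- 2 * pi * fk / fs
    a1 <- 2 * r * cos(theta)
    a2 <- -r^2
    gain <- (1 - r) * sqrt(1 - 2 * r * cos(2 * theta) + r^2)
    out <- numeric(n)
    y1 <- 0; y2 <- 0
    for (i in seq_len(n)) {
      out[i] <- gain[i] * y[i] + a1[i] * y1 + a2 * y2
      y2 <- y1
      y1 <- out[i]
    }
    y <- out
  }
  y <- y / max(abs(y))
  list(
    segment = speech_segment(y, fs, label = label,
                             subject_id = sprintf("synth-%d", spec$seed)),
    truth = downsample_track(truth, hop_ms = 2)
  )
}

# Reduce a per-sample track to the analysis hop grid.
downsample_track <- function(track, hop_ms) {
  hop <- hop_ms / 1000
  t_new <- seq(track$t[1], track$t[length(track$t)], by = hop)
  formant_track(
    t_new,
    stats::approx(track$t, track$f1, t_new, rule = 2)$y,
    stats::approx(track$t, track$f2, t_new, rule = 2)$y,
    valid = rep(TRUE, length(t_new))
  )
}

#' Synthesise a two-class cohort of AKV feature vectors
#'
#' Draws, per subject, `n_draws` velocity samples whose horizontal and
#' vertical components are zero-mean Gaussians (the subject SD is
#' log-normally jittered around the class sigma), so the speed magnitude
#' is Rayleigh and the squared speed follows a chi-squared distribution
#' with two degrees of freedom. Each subject's AKV magnitudes are then
#' histogrammed into the standard bin geometry and normalised to sum 1.
#' Pathological articulation decays slower, hence `sigma_path >
#' sigma_norm`.
#'
#' @param n_norm,n_path Number of normative / pathological subjects.
#' @param sigma_norm,sigma_path Class-level kinematic SD (cm/s).
#' @param n_bins,v_max,zero_bin_edge Histogram geometry (see
#'   [akv_config()]).
#' @param n_draws AKV samples per subject.
#' @param seed Integer seed; the cohort is fully reproducible from it.
#' @param subject_sd_jitter SD (log scale) of the per-subject spread
#'   around the class sigma.
#' @param keep_draws Keep the raw AKV draws per subject (needed for
#'   pairwise two-sample testing)?
#' @return A list with `features` (matrix, rows sum to 1), `labels`,
#'   `sigmas` (per-subject SD), `bin_edges`, and optionally `draws` (list
#'   of raw AKV vectors).
#' @export
synth_akv_cohort <- function(n_norm = 26, n_path = 53,
                             sigma_norm = 1.5, sigma_path = 3,
                             n_bins = 50, v_max = 25, zero_bin_edge = 0.05,
                             n_draws = 10000, seed = 1L,
                             subject_sd_jitter = 0.1,
                             keep_draws = TRUE) {
  if (sigma_norm <= 0 || sigma_path < sigma_norm) {
    stop_input("need sigma_path >= sigma_norm > 0")
  }
  if (n_draws < 10 * n_bins) {
    warning("n_draws < 10 * n_bins: histograms will be under-resolved")
  }
  edges <- akv_bin_edges(n_bins, v_max, zero_bin_edge)
  n_s <- n_norm + n_path
  labels <- c(rep("normative", n_norm), rep("pathological", n_path))
  class_sigma <- c(rep(sigma_norm, n_norm), rep(sigma_path, n_path))
  with_seed(seed, {
    sigmas <- class_sigma * exp(stats::rnorm(n_s, 0, subject_sd_jitter))
    draws <- lapply(seq_len(n_s), function(i) {
      vx <- stats::rnorm(n_draws, 0, sigmas[i])
      vy <- stats::rnorm(n_draws, 0, sigmas[i])
      sqrt(vx^2 + vy^2)
    })
    features <- t(vapply(draws, function(v) {
      akv_histogram(v, n_bins, v_max, zero_bin_edge)$p
    }, numeric(n_bins)))
    out <- list(features = features, labels = labels, sigmas = sigmas,
                bin_edges = edges)
    if (keep_draws) out$draws <- draws
    out
  })
}
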