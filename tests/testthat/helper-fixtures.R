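# Shared fixtures, built in code at load time.

# Small two-class AKV cohort used across classifier/detection tests.
fix_cohort <- synth_akv_cohort(
  n_norm = 10, n_path = 14, sigma_norm = 1.5, sigma_path = 3,
  n_draws = 2000, seed = 101, keep_draws = TRUE
)

# A stationary synthetic vowel plus its formant-tracking result.
fix_stationary <- local({
  sp <- vowel_spec(f0 = 110, formants = c(700, 1200, 2600),
                   tremor = tremor_spec(band_hz = 30), seed = 3)
  sv <- synth_vowel(sp)
  seg <- preprocess(sv$segment)
  list(spec = sp, vowel = sv, seg = seg, track = track_formants(seg))
})

# Labels helper for score sets.
mk_scores <- function(path, norm) {
  score_set(c(path, norm),
            c(rep("pathological", length(path)), rep("normative", length(norm))))
}

# Second-order resonator coefficients (recursive filter form).
resonator_coef <- function(f, bw, fs = 8000) {
  r <- exp(-pi * bw / fs)
  c(2 * r * cos(2 * pi * f / fs), -r^2)
}
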