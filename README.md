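# akvdetect

Detection of Parkinson-type hypokinetic dysarthria from sustained vowels,
via the kinematics of the jaw-tongue system as seen through the first two
formants.

## The idea

A healthy speaker can hold a sustained [a:] with the articulators almost
still; a speaker with hypokinetic dysarthria cannot — the jaw-tongue system
drifts and trembles, typically in a 5–8 Hz muscle-tension band, where
healthy phonation shows only small physiological tremor above ~25 Hz.
Because F1 and F2 track the position of a jaw-tongue reference point, that
instability is measurable from audio alone:

- Track F1(t), F2(t) by 9th-order linear prediction every 2 ms on a 500 ms
  segment at 8 kHz.
- Convert their derivatives (low-passed at 20 Hz) into reference-point
  velocities with calibration scales w₁₂ = 1.62·10⁻³ and
  w₂₁ = 1.47·10⁻³ cm·s, and form the **absolute kinematic velocity**

  |v(t)| = √[(w₁₂·df₂/dt)² + (w₂₁·df₁/dt)²]   (cm·s⁻¹)

- Describe each utterance by the normalised histogram of |v| — since the
  velocity components are ~zero-mean Gaussian, |v| is Rayleigh and |v|²
  follows a χ²₂ law; pathological speech decays slower.
- Classify the distributions with a **random least-squares feed-forward
  network** (fixed N(0,1) hidden layer, sigmoid kernel, Moore–Penrose
  least-squares output layer) read out as a log-likelihood-ratio score
  λ = log z_p − log z_n, and evaluate with ROC/AUC, DET, the equal error
  rate (EER) and its optimal threshold θ_rop, under leave-one-out and
  Monte Carlo protocols.

Clinical recordings are not distributable, so the package ships generators
for synthetic tremor vowels and for two-class χ²₂ feature cohorts; the
entire pipeline is validated against those. See
`vignettes/akv-methods.Rmd` for the model, the parameter table and the
design decisions.

## Worked example

```r
library(akvdetect)

# a synthetic vowel with 6 Hz pathological tremor, through the full chain
sp    <- vowel_spec(tremor = tremor_preset("pathological"), seed = 4)
sv    <- synth_vowel(sp, label = "pathological")
track <- track_formants(preprocess(sv$segment))
track
#> formant_track: 238 frames, hop 2 ms, 100% valid; median F1 = 697 Hz, F2 = 1201 Hz
kin <- akv_from_track(track)
kin
#> kinematic_track: 238 frames, median AKV 3.66 cm/s, max 6.21 cm/s
akv_histogram(kin$akv)
#> akv_distribution: 50 bins over [0, 25] cm/s, n = 238
#>   R1 0.000 | R2 0.351 | R3 0.649 | R4 0.000
```

The tracker recovers the synthesis targets (700, 1200 Hz) to a few Hz, and
the 6 Hz tremor shows up as AKV mass in region R3 (3–10 cm/s) — a
physiological-tremor vowel puts nearly all mass in R2 instead.

```r
# the cohort experiment: 26 normative vs 53 pathological subjects,
# sigma ratio 2, leave-one-out, then 20 Monte Carlo epochs
co <- synth_akv_cohort(n_norm = 26, n_path = 53, sigma_norm = 1.5,
                       sigma_path = 3, n_draws = 1e4, seed = 505,
                       keep_draws = FALSE)
detection_report(loo_run(co$features, co$labels, n_h = 200, seed = 1))
#> detection_report: AUC 1.0000, EER 0.0000 at theta_rop -0.0136
#>   at theta_rop: sensitivity 1.000, specificity 1.000, accuracy 1.000

monte_carlo(co$features, co$labels, n_epochs = 20, n_h = 200,
            master_seed = 606)
#> mc_report: 20 epochs, n_h = 200
#>   EER median 0.0000 [Q1 0.0000, Q3 0.0000]
#>   theta_rop median -0.0207 [Q1 -0.0281, Q3 -0.0140]
#>   median AUC 1.0000; cor(EER, theta) = NA (p = NA)
```

At this class separation the synthetic cohorts are essentially perfectly
separable (EER constant at 0 across epochs, so the EER–threshold
correlation is undefined and reported as NA); shrinking the sigma ratio
toward 1 degrades the EER monotonically, and shuffling the labels drops
the AUC to ~0.5. These synthetic figures validate the machinery — they are
not clinical performance claims.

## Command line

A thin wrapper over the same functions lives in `inst/cli/akv.R`:

```sh
Rscript inst/cli/akv.R synth vowel --class path --out v.wav --truth v.csv
Rscript inst/cli/akv.R extract v.wav --labels path --out features.csv
Rscript inst/cli/akv.R synth cohort --n-norm 26 --n-path 53 --out cohort.csv
Rscript inst/cli/akv.R classify cohort.csv --hidden 200 --seed 1
Rscript inst/cli/akv.R montecarlo cohort.csv --epochs 200 --hidden 200
```

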