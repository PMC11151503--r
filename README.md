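# phasormet

Single-cell metabolic imaging analysis for cells cultured on engineered
nanofiber scaffolds, in R. The package implements, as reusable and tested
functions, the quantitative pipeline used to ask whether the *alignment* of an
extracellular-matrix-mimicking fiber substrate shifts cellular metabolism and
phenotype:

- **Phasor FLIM of NADH.** Per-pixel TCSPC decay histograms (50 ns laser
  period, 256 time bins) are Fourier-projected onto harmonics of the
  repetition frequency, giving phasor coordinates
  `g_k = Σ c_j cos(ω_k t_j)/Σ c_j`, `s_k = Σ c_j sin(ω_k t_j)/Σ c_j` with
  modulation `m_k = √(g_k² + s_k²)` and phase `φ_k = atan2(s_k, g_k)`. After
  calibration against a lifetime standard (Atto 425, τ_ref = 3.6 ns), the
  multi-harmonic (m_k, φ_k) data are fitted by non-linear least squares to a
  two-component decay with a short *free*-NADH lifetime τ₁ and a long
  *bound*-NADH lifetime τ₂ with amplitude fractions α₁ + α₂ = 1. Reported
  per cell: the mean lifetime **τ_m = α₁τ₁ + α₂τ₂** and the **NADH metabolic
  index α₁(free)/α₂(bound)** — higher index means a larger free-NADH pool,
  i.e. a more glycolytic state.
- **Optical redox ratio (ORR).** From two-photon NADH and FAD intensity
  channels, per pixel **ORR = I_FAD / (I_FAD + I_NADH)** (1 ≈ oxidative
  phosphorylation, 0 ≈ glycolysis), with Rhodamine-B reference normalization
  and nucleus-excluded per-cell aggregation.
- **Per-cell quantification.** Nuclei detected by global minimum
  cross-entropy (Li) thresholding, whole cells by seeded propagation,
  integrated intensity (vimentin, 2-NBDG), baseline-normalized fold change,
  and nuclear **circularity = 4π·area/perimeter²** with a multi-direction
  Crofton perimeter estimator.
- **Scaffold characterization.** Structure-tensor fiber-orientation
  distributions, **Herman's orientation index S = 2⟨cos²θ⟩ − 1** (1 = fully
  aligned, 0 = fully random), skeleton-based fiber diameters, and Young's
  modulus from stress–strain records.
- **Expression and statistics.** Relative qPCR expression by **2^−ΔΔCt**
  (ACTB housekeeping), Welch's and Student's t tests, the two-sample
  Kolmogorov–Smirnov test, and SEM summaries.

Every input the pipeline consumes can be generated by the package's own
synthetic-data module with known ground truth — decay histograms with Poisson
photon statistics, two-channel cell fields, fiber mats with controllable
orientation concentration, Ct tables and stress–strain curves — so the entire
analysis is testable end to end with no external data.

## Worked example

Fit the free/bound NADH model to a simulated noisy decay and report the
metabolic index:

```r
library(phasormet)

# calibrate against an ideal 3.6 ns lifetime standard
ref <- simulate_decay(decay_sim_spec(3.6, 1, total_photons = 1e6))
cal <- build_calibration(ref, tau_ref_ns = 3.6, harmonics = 1:8)

# a 5,000-photon decay with 70% free NADH (0.4 ns) and 30% bound (2.5 ns)
h <- simulate_decay(decay_sim_spec(c(0.4, 2.5), c(0.7, 0.3),
                                   total_photons = 5000,
                                   noise = "poisson", seed = 1))
fit <- fit_biexponential(apply_calibration(phasor_transform(h, 1:8), cal))
fit
#> <biexp_fit> tau1 0.4266 ns (alpha1 0.698), tau2 2.508 ns (alpha2 0.302)
#>   mean lifetime 1.056 ns, metabolic index 2.309, residual 0.00654
```

The recovered amplitude fraction (α₁ ≈ 0.70) and lifetimes match the
simulated truth within shot noise; the metabolic index 2.31 ≈ 0.70/0.30
quantifies the programmed glycolytic state.

A complete two-condition in-silico study (aligned vs random scaffolds, with
programmed metabolic, phenotypic and architectural effects) runs in seconds:

```r
res <- run_study(study_spec(), seed = 1, out_dir = "study_out")
res$comparisons[, c("metric", "test", "mean_a", "mean_b", "p_value")]
#>                          metric      test    mean_a    mean_b      p_value
#> metabolic_index metabolic_index        ks 2.4325280 2.0840639 1.701193e-04
#> mean_orr               mean_orr        ks 0.2742808 0.3079322 2.489408e-07
#> vimentin               vimentin student_t 50503.175 45183.942 2.988288e-06
#> circularity         circularity student_t 0.5879682 0.7603694 1.771259e-68
#> modulus                 modulus   welch_t 1.3919584 0.8755557 3.949447e-05
#> ...
```

(`mean_a` is the aligned condition, `mean_b` the random baseline; the study
reproduces the programmed directions — index up, ORR down, vimentin up,
circularity down on aligned — and flags each with its configured test.)

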