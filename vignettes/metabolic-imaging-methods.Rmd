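---
title: "Methods: phasor FLIM, redox imaging and scaffold morphometry in phasormet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phasor FLIM, redox imaging and scaffold morphometry in phasormet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phasormet)
```

`phasormet` analyzes single-cell metabolic imaging experiments on engineered
nanofiber scaffolds. This vignette documents the models, the numerical
choices, and what the synthetic-data generators do and do not emulate, so
that results from the test suite can be interpreted correctly.

## Decay simulation and the phasor transform

Fluorescence decays are modeled as ideal truncated multi-exponentials over
one laser repetition period *T* (default 50 ns) divided into *N* time bins
(default 256) — the layout of a digital frequency-domain FLIM instrument.
The bin value is the *integral* of the decay over the bin, matching
photon-counting physics, not a midpoint sample. Two idealizations are
deliberate:

- **No instrument response function.** Real instruments fold the decay with
  an IRF; the calibration step removes it together with other instrumental
  phase/modulation distortions. The simulator's "instrument" is ideal, so
  the calibration contract can be tested in closed form.
- **No periodic wrap-around.** Decays are truncated at *T*. For lifetimes up
  to 9 ns and *T* = 50 ns the wrapped tail is below e^-5 of the peak.
  Because the harmonics are periodic in *T*, truncation cancels exactly in
  the continuous phasor integral, so this costs nothing in phasor space.

The phasor transform evaluates, at harmonic *k* (angular frequency
ω_k = 2πk/T), the cosine and sine projections of the histogram on the bin
*centers*. For a binned mono-exponential this discrete phasor has an exact
closed form: with z = exp(-Δ/τ) and b = ω_kΔ (Δ the bin width),

G_disc(τ) = e^(ib/2) (1 - z) / (1 - z e^(ib)),

which differs from the continuous phasor 1/(1 - iω_kτ) by a τ-dependent
factor of order b². At 256 bins this discretization displaces phasors by up
to ~1e-4 (harmonic 1) to ~7e-3 (harmonic 8).

## Calibration and the universal circle

`build_calibration()` compares the measured phasor of a lifetime standard
(Atto 425, τ_ref = 3.6 ns) with the theoretical mono-exponential values
m = 1/√(1+(ωτ_ref)²), φ = atan(ωτ_ref) and stores a per-harmonic modulation
scale and phase offset. Applying it to the reference reproduces the
theoretical point exactly; applied to unknown decays it removes
instrumental (and, for synthetic data, most discretization) distortion.

Calibrated mono-exponentials lie on the *universal circle*
(g - 1/2)² + s² = 1/4. This is a continuum identity: a two-parameter
(scale, offset) correction anchored at one reference lifetime cannot cancel
the τ-dependent part of the binning factor, so at 256 bins calibrated
single exponentials sit within ~5e-5 of the circle, not on it. The test
suite therefore verifies the identity in a bin-refinement study (4096 bins,
residual < 1e-6, consistent with the ~1/N² scaling) and separately asserts
the documented 256-bin floor (< 1e-4). Quantitative fitting does not rely
on the circle: see next section.

## Two-component (free/bound NADH) fitting

NADH is short-lived when free in the cytosol (~0.4 ns) and long-lived when
protein-bound (~1.4-9 ns). `fit_biexponential()` minimizes

Σ_k [(m_k^obs - m_k^model)² + w (φ_k^obs - φ_k^model)²],  w = 1,

over (τ₁, τ₂, α₁), where the model phasor is the intensity-weighted sum of
component phasors, with intensity fractions f_i ∝ α_i τ_i (the amplitude →
intensity conversion; truncation-corrected for the binned model). Key
choices:

- **Measurement model.** The default forward model is the exact binned
  phasor G_disc above, composed with the calibration factor carried by
  calibrated phasor sets. This makes the simulate → transform → calibrate →
  fit round trip exact to optimizer precision (~1e-8 relative across the
  grid α₁ ∈ {0.1..0.9} × τ₁ ∈ {0.3, 0.4, 0.6} × τ₂ ∈ {1.4, 2.5, 9} ns),
  because the model and the data share the same discretization. The classic
  continuous model (`model = "continuous"`) is available when binning is
  negligible; with it, the residual discretization bias at 256 bins
  propagates to parameter errors of order 1e-3-1e-2.
- **Harmonics.** Default harmonics 1-8 of the 20 MHz fundamental: 16
  observations for 3 parameters, a well-posed non-linear least squares.
  Configurable.
- **Bounds and starts.** τ₁ ∈ [0.1, 1] ns, τ₂ ∈ [1, 9] ns — the stated
  physiological free/bound ranges — with five deterministic multi-starts
  and an L-BFGS-B polish using a fine finite-difference step (the default
  step is too coarse to localize the minimum of this very flat, very small
  objective). τ₁ < τ₂ is enforced by sorting; fits with τ₂ - τ₁ < 0.05 ns
  or α₁ at a boundary carry a `degenerate` flag.
- **α in the metabolic index** is the amplitude (pre-exponential) fraction,
  the standard reading of "fractional contribution"; the intensity-fraction
  alternative can be obtained from the fit but is not the default.
- **Per-cell pooling.** `per_cell_flim()` sums the histograms of qualifying
  pixels (default ≥ 100 photons) per cell before transforming and fitting.
  Photon-limited per-pixel bi-exponential fits are unstable; pooling matches
  cell-level reporting. Per-pixel *phase lifetime* maps are provided for
  display only.

Derived quantities: mean lifetime τ_m = α₁τ₁ + α₂τ₂ and metabolic index
α₁/α₂ (larger = more glycolytic). The default per-pixel photon budget of
the simulator (5,000 photons) is a package choice for a realistic
acquisition; at that level the median α₁ recovery error over 200 Poisson
replicates is well inside 0.05.

## Optical redox ratio

ORR = I_FAD/(I_FAD + I_NADH) per pixel. Undefined pixels (zero denominator)
are masked, never imputed — imputation would bias per-cell means. Per-cell
aggregation averages over cell-minus-nucleus pixels (cells with fewer than
20 qualifying pixels are dropped with a warning); background pixels are
excluded via segmentation in the quantification path, while scalar
background *subtraction* (negatives clipped) is available for
visualization. Reference-dye normalization divides a channel by the spatial
mean of a Rhodamine-B reference acquired at the same settings and is applied
per channel (whether the original protocol normalized per channel or per
session is not stated; per-channel is the assumption here). The ratio is
scale-invariant under joint gain changes after normalization. A seeded
`subsample_cells()` reproduces protocols that analyze a random subset of
cells per field.

## Segmentation and morphometry

- **Thresholding.** Global minimum cross-entropy (Li) thresholding,
  implemented as exact minimization of the cross-entropy objective over a
  256-level histogram. The objective's valley between well-separated modes
  is nearly flat; tests therefore check attainment of the optimum value,
  not a specific threshold location.
- **Nuclei.** Threshold → connected components → size filter (defaults
  50-10,000 px, configurable) → distance-transform watershed declumping
  with a 2 px smoothing scale.
- **Cells.** Seeded propagation from nuclei: foreground is the Li threshold
  of the cytoplasmic channel united with the nuclei; pixels are assigned by
  minimal cumulative cost, a step of length d across an intensity change dI
  (on a [0,1]-normalized scale) costing d·√(1 + (dI/α)²) with α = 0.05.
  With uniform intensity this reduces to geodesic nearest-seed assignment,
  verified against a brute-force shortest-path oracle.
- **Circularity.** 4π·area/perimeter², perimeter by a Cauchy-Crofton
  estimate: boundary crossings counted along 12 families of parallel
  digital lines (axis, diagonal, knight-move (2,1) and (3,1) directions),
  weighted by line spacing and trapezoidal angular coverage. The common
  4-direction variant is exact for disks but biases axis-aligned squares
  ~5% low, and naive pixel-edge counting biases disks so badly that a
  perfect circle scores ~0.62; the 12-direction default is within ~1% on
  disks, squares and ellipses (ellipse oracle: Ramanujan's perimeter
  approximation). Values are clipped at 1.0 for reporting (discretization
  can push a large disk marginally above 1), the raw value is retained, and
  single-pixel objects are flagged undefined. All nuclei are measured; a
  seeded subsample reproduces manual ROI protocols.

## Fiber architecture and mechanics

Orientation is computed per pixel from the 2×2 structure tensor (derivative
scale 1 px, tensor smoothing 3 px), with weights = coherence × gradient
energy and low-energy background excluded (default: below 5% of the peak
energy). Angles follow one convention everywhere: degrees in [-90, 90),
0° along the image x-axis, counter-clockwise positive. Herman's index is
the 2D form S = 2⟨cos²θ⟩ - 1 (S = 1 aligned, 0 random, -1 perpendicular to
a fixed axis), the form whose endpoints are exact for 2D projections of
fiber mats; the 3D variant is available by flag. When no reference axis is
given it is set to the principal direction — the maximizer of S, computed
from the resultant of the doubled angles — which makes S rotation-invariant
and confined to [0, 1]. Per-traced-fiber orientation is not used: the
tensor route is robust to fiber crossings and is validated against the
generator's per-fiber ground truth. Synthetic mats render anti-aliased
straight fibers spanning the field (compositing by maximum, as occluding
fibers appear in SEM); heavily occluded scenes (coverage → 1) lose
orientation information at crossings, so flatness checks use moderate
coverage. Wrapped-normal orientation sampling uses standard deviation
1/√κ radians; S is monotone in κ, and the study defaults κ = 8.5 / 3.0
correspond to the aligned/random architectures (S ≈ 0.79 / 0.51) of the
system being modeled.

Fiber diameter: Li threshold → Zhang-Suen skeleton → 2 × Euclidean distance
transform at skeleton pixels, in µm via the pixel size; unbiased within
discretization (≤ 10% for widths ≥ 6 px) on straight noiseless fibers.

Young's modulus is the least-squares slope of stress vs strain over the
linear region; automatically, the maximal leading window (≥ 5 points) with
R² ≥ 0.99. Near a yield plateau that criterion can admit a few post-yield
points (slope then underestimates by a few percent); passing an explicit
`linear_region` fits exactly the requested window, which is what the
orchestrated study does for its purely linear synthetic records.

## Expression and statistics

2^-ΔΔCt uses the condition-mean convention: ΔCt = Ct_target − Ct_housekeeping
per sample (technical replicates averaged), ΔΔCt as the difference of
condition means against the baseline, with per-sample fold changes also
emitted for dispersion. Housekeeping is ACTB by default; samples missing it
are dropped with a warning.

`compare_groups()` computes Welch's t (Welch-Satterthwaite df), Student's
pooled t, and the two-sample KS test from first principles; the reference
implementations in `stats` serve as oracles in the tests, not as the
implementation. The KS p-value uses exact lattice-path enumeration when both
groups have n < 10 and no ties, and otherwise the asymptotic Kolmogorov
series with Stephens' finite-sample factor λ = (√n_e + 0.12 + 0.11/√n_e)·D —
the standard finite-n form, chosen because cell-level group sizes around 10
sit exactly where the bare asymptotic formula is least accurate. Under
10,000 null simulations at n = 10 per group all three tests hold their
empirical type-I error within [0.04, 0.06] at α = 0.05. Both-groups-constant
with equal means returns p = 1 by convention. Percent change is defined
against the stated baseline group. No multiple-testing correction is applied
(per-comparison reporting, matching the modeled study design);
`p.adjust`-style correction can be layered on by the caller.

## The synthetic study and its scope

`run_study()` wires everything into a two-condition experiment (aligned vs
random scaffolds) with programmed effects: metabolic index +14% via α₁ 0.680
→ 0.708 (per-cell SD 0.012, 10 cells per condition), ORR 0.31 → 0.27
(per-cell SD 0.015, 20 cells), vimentin +13% and 2-NBDG +25% (per-cell
lognormal CV 10%, ~36 cells), nuclear axis ratio 2.5 → 3.7 (circularity
≈ 0.75 → 0.58), fiber concentration κ 3.0 → 8.5 with widths 0.54 → 0.46 µm,
moduli 0.88 → 1.39 MPa, and qPCR fold changes (VIM 1.5, CDH1 0.8, SNAI1
1.86, CD44 8.48, MMP2 2.25; Ct noise SD 0.15, triplicates). Field sizes
(64-192 px) and cell counts are scaled so the full study runs in seconds
while keeping every effect several standard errors wide; the weakly
programmed CDH1 effect (≈ 1.9 SE at triplicate scale) is not reliably signed
and is reported but not asserted. All stage seeds derive deterministically
from one master seed; identical config + seed gives byte-identical JSON
reports.

What the generators do *not* emulate: optical point-spread functions,
photobleaching, motion, 3D scaffold structure, spectral bleed-through
(including the FMN/FAD confounder of intensity-based redox imaging), or
cell-shape irregularity beyond circular cells with elliptical nuclei.
Passing tests therefore demonstrate correctness of the *computations* under
controlled conditions, not robustness to every artifact of real microscopy
data.

## Interfaces

Images travel as 32-bit float TIFF (with a small JSON sidecar recording the
intensity scale), label maps as 16-bit TIFF, FLIM stacks as multi-frame
TIFF (one frame per time bin) plus a JSON sidecar with the period and bin
count; tables as CSV and reports as JSON. The package functions are the
primary interface; `inst/scripts/run_study.R` is a thin command-line wrapper
over `run_study()`, and `scripts/acceptance.R` recomputes the headline
verification quantities from scratch.
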