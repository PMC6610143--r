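---
title: "Models and methods behind spottrackr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind spottrackr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spottrackr)
```

spottrackr analyses live-cell single-molecule imaging data: movies of
diffraction-limited fluorescent spots (single tagged proteins, mRNA
translation sites, nuclei in a developing embryo) and the kinetic traces that
accompany such experiments (photobleaching recovery, surface-binding
sensorgrams). This vignette explains the models each stage assumes, the
tunable parameters and their defaults, what the synthetic-data generator does
and does not emulate, and the numerical choices that were genuinely open.

## Coordinate and unit conventions

Pixel coordinates are 0-based with `x` = column and `y` = row; the origin is
the *centre* of the top-left pixel. Every public table carries both pixel and
micrometre coordinates, converted by the movie's `pixel_size_um`; all
positions handed to the tracking and mobility layers are in micrometres, so
the physics (µm²/s, µm/s, nm gates) never depends on camera magnification.
Defaults mirror common hardware: 0.13 µm pixels for the ×100 single-molecule
configuration and 0.662 µm pixels for the low-magnification embryo imaging.

## Synthetic data: what it emulates

The generator produces every input the pipeline consumes, with known ground
truth, which is how all quantitative claims in the test-suite are validated.

* **Motion** (`make_tracks()`): Brownian motion with per-axis Gaussian
  increments of variance $2D\,\Delta t$; bound emitters anchored with
  Gaussian jitter (default 30 nm, the scale of chromatin-bound molecules plus
  localization error); motored tracks alternating diffusive pauses with
  directed runs (duration, speed, heading), since transported particles show
  both behaviours within one trajectory. Boundaries reflect, keeping density
  uniform without birth/death bookkeeping. An optional `mobility_field`
  scales $D$ by position to emulate spatially structured mobility (e.g.
  reduced mobility at the nuclear periphery).
* **Camera** (`render_movie()`): each visible emitter is a symmetric 2-D
  Gaussian of width `psf_sigma_px` (default 1.0 px ≈ a diffraction-limited
  PSF at 130 nm pixels) and peak amplitude `photons_per_spot` on a constant
  background; noise is Poisson on the expected signal plus Gaussian read
  noise, then rounded to integer counts as a real camera digitizes. This is
  the simplest model that makes localization error realistic. The paper
  trail for real data rarely states amplitudes, so defaults are chosen for
  solvable localization (SNR roughly 5–20), not to match any particular
  instrument.
* **Photo-switching** (`photo_kinetics()`): emitters may start dark,
  activate at periodic pulses with a per-pulse probability, and bleach at a
  first-order rate — the ingredients of photoactivated sparse tracking.
* **FRAP traces** (`make_frap_trace()`): pre-bleach plateau at 1, an
  instantaneous drop by `bleach_depth`, recovery
  $I(t) = I_0 + m_f\,\beta\,(1-e^{-kt})$, and a whole-compartment reference
  decaying as $e^{-\lambda t}$ to emulate acquisition bleaching — exactly
  the factor double normalization must cancel.
* **Sensorgrams** (`make_sensorgram()`): the closed-form one-to-one Langmuir
  kinetics (below) plus additive Gaussian noise.
* **Run-off scenes** (`make_runoff_scene()`): after drug addition each
  nascent-chain spot disappears with an exponential waiting time at
  `runoff_rate`, so the expected surviving fraction is
  $e^{-r(t-t_{\text{drug}})}$, while the mRNA channel persists.
* **Embryos** (`make_embryo_sequence()`): disk-shaped nuclei that double in
  number every `division_period_frames` (radius divided by $\sqrt 2$, so
  area halves), drift slowly, and are kept mutually separated by a small
  relaxation step so that neighbouring nuclei remain individually
  segmentable; a probe channel whose true nuclear-to-cytoplasmic ratio
  follows a configurable ramp (default 1 → 2.5).

What the generator does **not** emulate: 3-D PSFs, pixel-dependent sCMOS
noise, chromatin texture, cell shape, out-of-focus light, vesicle
autofluorescence, or biological heterogeneity between cells. Passing tests
therefore demonstrate algorithmic correctness under the stated noise model,
not performance on any particular real dataset.

## Localization

Detection is bandpass → binarize → centroid: a difference of Gaussian blurs
(defaults σ = 1 and 3 px, a passband sized to spots; the kernel sizes are a
declared choice, not inferred from data), thresholded at mean + 3 SD of the
bandpassed frame (Otsu available), connected components of at least
`min_area` = 3 px², each reduced to its intensity-weighted centroid.

Refinement fits the elliptical Gaussian
$I(x,y) = I_{BG} + I\,e^{-(x-x_0)^2/2\sigma_x^2-(y-y_0)^2/2\sigma_y^2}$
by Levenberg–Marquardt over a window of half-width 5 px, initialized at the
centroid with moment-based widths. Degenerate (flat) windows and stalled
optimizations return `converged = FALSE` rather than erroring, and
`localize_movie()` falls back to the detection centroid for those spots. The
fit is exactly invariant to adding a constant to the window (absorbed by
$I_{BG}$), and on noiseless rendered spots recovers all five parameters to
better than 10⁻³.

Drift is estimated per frame by the peak of the FFT cross-correlation
against a reference frame, refined by quadratic peak interpolation
(sub-pixel); featureless frames report zero drift with a low-confidence
flag. Camera-to-camera registration pairs fiducial localizations by mutual
nearest neighbour within a 3 px gate and fits translation, similarity
(closed-form SVD solution) or affine least squares; residual RMSE never
increases with model complexity on the same pairs.

## Tracking and the bound-molecule filter

Linking is nearest-neighbour with a hard displacement gate: for each frame
transition, candidate pairs within `max_disp` are accepted greedily in
ascending distance, one-to-one; remaining localizations seed new tracks.
Ties are broken by sorted position so the result is deterministic and
independent of input row order. `memory_frames = 0` by default — no gap
closing — because the downstream bound filter requires strictly consecutive
frames, making gapped tracks useless. Two gates matter: 0.22 µm/frame for
fast sparse single-molecule imaging (reusing the bound-filter jump gate) and
~1.5 µm/frame for slow translation-site movies.

The bound filter keeps tracks with at least 16 consecutive frames whose
frame-to-frame jumps are *all* under 220 nm — the standard criterion for
separating chromatin-bound from freely diffusing molecules. On simulated
mixtures (30 nm jitter bound vs $D = 0.5$ µm²/s free at a 43.8 ms cadence
with photoactivation-limited track lengths) the filter recovers > 80% of
bound emitters with < 1% false positives, and a bound-target simulation
yields tens of times more filtered tracks than a no-target control.

## Mobility

`ensemble_msd()` uses the time-averaged-then-ensemble convention: each
track's MSD is averaged over all ordered frame pairs at a lag, then the
curve is the unweighted mean across tracks with the across-track SEM as the
error bar — so error bars reflect particle-to-particle variability.
`fit_diffusion()` fits an ordinary least-squares line with free intercept to
the first five non-zero lags; the intercept absorbs static localization
error, and $D = m/4$ for 2-D Brownian motion.

The 95% CI on $D$ is computed by a delete-one jackknife over tracks rather
than from the OLS residuals: the five MSD points share the same tracks and
are strongly correlated, so residual-based standard errors are an order of
magnitude too small and their CIs grossly under-cover. The jackknife CI
achieves close to nominal coverage in simulation (≈93% across seeded
replicates at the 401-track scale). Under clean Brownian conditions its
half-width is a few 10⁻⁴ µm²/s at $n = 401$ tracks of 30 frames; real-data
CIs are typically wider because track lengths vary and particles are
heterogeneous.

Directed transport: instantaneous speeds are displacement rates smoothed by
a 3-frame centred moving average; an event is ≥ 3 consecutive smoothed
samples above 1 µm/s (the conventional motor-transport threshold — the
event definition itself is this package's choice). The event's mean speed
is its raw path length divided by its duration, because smoothing dilutes
boundary samples and would bias the speed low.

## Kinetics

FRAP uses double normalization,
$\big(I_{roi}(t)/\bar I_{roi}^{pre}\big) \big/
 \big(I_{whole}(t)/\bar I_{whole}^{pre}\big)$,
after background subtraction: the whole-compartment ratio cancels
acquisition bleaching shared by both series, and the pre-bleach mean is 1 by
construction. The double variant was chosen because both bleach-spot and
whole-compartment intensities are recorded in these experiments; a
full-scale variant (ignoring the reference) is available behind
`method = "full_scale"`. Recovery is fitted as
$I(t) = I_0 + A(1-e^{-kt})$ (single exponential by default — the choice is
deliberate and logged here; a double-exponential option exists), and $t_½$
is read from the *fitted* curve (time to half the recovered amplitude;
$\ln 2/k$ for the single model) for robustness to noise. A fit whose
amplitude is indistinguishable from zero reports `t_half = NA`.

SPR association follows
$R(t) = R_{eq}\,(1-e^{-(k_{on}C + k_{off})t})$ with
$R_{eq} = R_{max}\,C/(C + K_D)$, and dissociation decays as
$e^{-k_{off}t}$. `fit_binding()` fits all concentrations globally with
shared $k_{on}$, $k_{off}$, $R_{max}$ (rates parameterized on the log scale
for positivity); per-curve fits are available for diagnostics, and
`fit_dissociation()` gives the log-linear $k_{off}$ from a dissociation
phase alone. A single concentration with no dissociation phase is rejected
as unidentifiable. $K_D = k_{off}/k_{on}$ holds to machine precision by
construction.

## Region quantification

Nuclear segmentation is threshold (Otsu by default; the appropriate
threshold is data-dependent and therefore a logged parameter, not a
constant) → connected components → minimum-area filter. Cytoplasmic rings
are built with an *exact Euclidean* distance transform rather than an
iterated structuring element: the ring of a nucleus is the set of pixels at
morphological distance in (1, 4] px from it (defaults 4 px outer, 1 px inner
dilation). Pixels within the inner dilation of *any* nucleus are excluded,
rings clip at frame edges, and a pixel reachable from two nuclei belongs to
the nearer one (ties to the lower label) — a deterministic assignment
verified against brute-force pixel enumeration.

Ratios are means of raw counts: nuclear-to-cytoplasmic uses each nucleus's
ring; signal-to-background uses a caller-supplied background region, because
"background" is experiment-specific. The fold change between two group means
uses the first-order delta method,
$\mathrm{SEM} = |r|\sqrt{(s_1/m_1)^2 + (s_2/m_2)^2}$.

Run-off curves self-normalize each cell by its own pre-drug mean before
averaging across cells (cell-to-cell SEM), so the pre-drug segment is 1 by
construction and cells with different expression levels are comparable.
Distribution summaries use linear-interpolation quantiles (R type 7) for
the median, 25–75% box and 5–95% whiskers — stated because box-whisker
panels depend on the interpolation rule.

Nucleus lineages are tracked by mask overlap: each nucleus is matched to
the previous-frame nucleus whose 4 px-dilated mask overlaps it most (ties
to the lower label); one child continues the lineage, several children
record a division with the parent lineage noted. Max-projection (2-D)
segmentation only — matching how such embryo data are typically quantified —
and no watershed splitting of touching nuclei, which is why the generator
keeps nuclei separated.

## Problem sizes and numerical choices

The validation suite runs entirely on synthetic data at sizes chosen to make
Monte-Carlo error small relative to the tested tolerances while keeping the
suite fast: 10⁴ jumps for jump-variance checks, 401/285 tracks × 30 frames
for diffusion recovery (100 seeded replicates for the coverage check),
64–192 px fields with ≤ 20 emitters for localization oracles, 12 noisy
traces for FRAP spread, 10 cells × 40 spots for run-off, and a 21-frame
embryo spanning two division rounds. Optimizers are Levenberg–Marquardt
(`minpack.lm`) with moment-based or closed-form initializations; fits report
failure flags instead of raising; random number use is always governed by an
explicit seed argument, and every generator is bit-reproducible for a fixed
seed.

## Known limitations

* Localization is least-squares, not maximum-likelihood; at very low photon
  counts an MLE would be more precise.
* No gap closing in the linker; blinking emitters fragment into several
  tracks (harmless for the bound filter, which forbids gaps anyway).
* The diffusion fit assumes free 2-D Brownian motion over the first five
  lags; anomalous exponents and confinement are out of scope.
* FRAP fitting is reaction-limited (exponential); diffusion-coupled
  recovery models are not implemented.
* Ring-based cytoplasmic sampling assumes the perinuclear region is
  representative cytoplasm; it is blind to cytoplasmic organelles inside
  the ring.
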