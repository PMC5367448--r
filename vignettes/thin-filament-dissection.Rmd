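---
title: "Dissecting thin-filament regulatory states in intermediate-resolution density maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting thin-filament regulatory states in intermediate-resolution density maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thinfilament)
```

## The scientific problem

Striated-muscle contraction is regulated by the thin filament: F-actin
decorated with two continuous tropomyosin strands and, once per seven
actin subunits per strand, a troponin complex.  In the steric-blocking
model, tropomyosin's azimuthal position on actin gates myosin binding:
the **blocked (B)** position covers the myosin sites (low Ca²⁺), the
**closed (C)** position partially exposes them (Ca²⁺ bound), and the
**myosin/open (M)** position exposes them fully.  At the ~28 Å
resolution typical of negative-stain single-particle reconstructions of
thin filaments, these positions differ by azimuthal rotations of a few
tens of degrees about the filament axis — measurable, but only with
careful model-based analysis.

This package implements that analysis as a tested pipeline:

1. **Model building** (`build_actin_filament()`, `add_tropomyosin()`,
   `add_troponin()`, `functional_unit()`): parameterised pseudo-atomic
   models of the two-start actin helix, tropomyosin strands with
   per-pseudo-repeat azimuthal offsets, and staggered troponin
   complexes.
2. **Density simulation** (`render_map()`, `add_noise()`,
   `half_map_pair()`): EM-like maps at a stated resolution with
   controlled noise — the synthetic stand-ins for experimental
   reconstructions, with known ground truth.
3. **Docking** (`global_fit()`, `local_segment_fit()`,
   `rank_candidate_models()`): rigid-body fitting, first of the whole
   filament, then of three-subunit tropomyosin segments, one per actin
   subunit.
4. **Dissection** (`subtract_component()`, `segment_component()`):
   two-stage difference mapping — subtract docked actin to reveal
   tropomyosin + troponin, then actin + tropomyosin to isolate
   troponin.
5. **Quantification** (`rotation_from_blocked()`, `classify_state()`,
   `group_means()`, `troponin_stagger()`, `axial_span()`, `fsc()`,
   `residue_displacement()`): the headline numbers.
6. **Orchestration** (`pipeline_config()`, `run_pipeline()`,
   `make_fixtures()`, `parameter_recovery()`): a single-seed,
   fully deterministic end-to-end run.

## The lattice model and its conventions

Every geometric statement derives from `helical_params()`:

* **rise** = 27.5 Å per genetic-helix subunit.  This is the canonical
  F-actin axial rise and equals the axial stagger between equivalent
  features on the two long-pitch strands.
* **twist** = −166.67° per subunit (left-handed genetic helix, close to
  13/6 symmetry).  Reconstructions of this kind do not constrain the
  twist strongly and published analyses rarely state it; the value here
  is the field's conventional one and is configurable.  Long-pitch
  neighbours along one strand are related by (2·rise, 2·twist), i.e.
  55 Å and +26.7° (mod 360°), producing the familiar slowly twisting
  two-strand appearance.
* **actin_radius** = 25 Å and **tm_radius** = 39 Å are
  literature-typical radial positions of the actin subunit centre of
  mass and the tropomyosin coiled-coil axis.  Neither is a measured
  quantity here; both are configurable and all reported azimuths are
  relative, so the analysis is insensitive to their exact values.

Azimuth conventions: the blocked-state tropomyosin azimuth is the
reference (0°) **by construction** — every reported rotation is
relative, because only relative rotations are observable in the data
this emulates.  Positive rotations move tropomyosin from the
outer-domain (blocked) azimuth toward the inner-domain (M-state)
azimuth, viewed from the pointed end.  The barbed (Z-band) end is at
low axial coordinate.

Models are bead models: ~11 beads per actin subunit, tropomyosin beads
every 5.5 Å along the strand, an ellipsoidal troponin core plus a
linear TnT1 tail running along tropomyosin toward the pointed end over
two long-pitch subunits (110 Å).  At 28 Å resolution bead and atomic
models render indistinguishably (the test suite checks ≥ 0.98
correlation for a refined bead cloud), so atomic PDB input is
interchangeable via `read_model_pdb()`.

Per-repeat azimuthal offsets (`repeat_azimuths()`) are keyed by the
subunit labels `a`–`g` of the functional unit: `c` and `d` flank the
troponin core, `a`–`b` lie on the barbed side, `e`–`g` on the pointed
side.  Offsets are interpolated **linearly in the axial coordinate**
between adjacent repeat centres, so the strand stays continuous, and
extended periodically to flanking repeats (a long filament repeats its
regulatory pattern).  The canonical state offsets are
`state_offsets()`: B = 0°, C = 18°, M = 28° — the mean rotations
reported for Ca²⁺-treated filaments on the pointed (d–g) and barbed
(a–c) sides of troponin.  The mixed-state default of
`pipeline_config()` (a–c at 28°, d–g at 18°) is the Ca²⁺-treated
condition this package's acceptance surface reproduces.

The troponin complex **rides at the local tropomyosin azimuth** of its
strand (it is tropomyosin-bound), with the core just outside the
tropomyosin radius and the strand-2 complex offset axially by one
genetic rise (27.5 Å) by default — the stagger observed between
troponin densities on the two strands.

## Density simulation

`render_map()` places a normalised isotropic Gaussian on every bead.
The width convention must be stated, since "resolution" has no unique
operational meaning for model maps: we choose σ such that the Fourier
amplitude falls to 1/e at spatial frequency 1/resolution, i.e.
σ = resolution/(√2 π) ≈ 6.3 Å at 28 Å.  Gaussians are truncated at
4.5 σ, keeping the map integral equal to the total bead weight within
well under 1%.

Default sampling is a 4 Å voxel (7× oversampled at 28 Å).  A 96×96×96
box holds a bare 14-subunit functional unit; the pipeline default is
96×96×144 because localised fitting of the terminal repeats needs
flanking subunits and the continuous tropomyosin strand extending past
them, and the 20-subunit filament used for stagger measurements gets
96×96×160.  These box sizes are the package's own choice and keep every
end-to-end run fast.

Noise is white Gaussian in real space, calibrated so that the variance
ratio of signal to noise *within the filament envelope* (voxels above
2% of the clean maximum) equals the requested SNR; the default SNR of 2
produces maps on which all acceptance quantities remain recoverable,
emulating a well-averaged negative-stain reconstruction.  Contrast is
treated as already normalised (protein positive).  What this generator
deliberately does **not** emulate: CTF effects, stain-envelope
flattening and one-sidedness, projection/reconstruction anisotropy,
flexibility-induced local blurring, and reference-based alignment bias.
Passing recovery tests on these maps therefore demonstrates that the
measurement machinery is unbiased and noise-robust under the stated
model, not that every property of real negative-stain data is handled.

Maps are written and read as MRC2014, mode 2 (32-bit float), with the
origin recorded both in the ORIGIN words and in nstart for maximum
reader compatibility; the test suite cross-checks the format against an
independent reader (Python gemmi).

## Docking

Scoring is the Pearson correlation between the map and the rendered
density of the posed model over a mask of voxels near the model
(`score_fit()`, mask radius 12 Å — wide enough to include the feature's
density at 28 Å, narrow enough not to bleed into neighbouring
components).  Pose searches are **cylindrical** (azimuth about the
filament axis, axial shift, and for segments a radial shift) rather
than full SO(3): tropomyosin's regulatory movement is azimuthal, and the
filament frame is fixed by the global fit.  Full grids are scanned
exhaustively and deterministically; the only sub-grid step is a
three-point parabolic interpolation of the score surface about the grid
optimum, applied per axis.

`local_segment_fit()` implements the per-subunit stage: the tropomyosin
segment spanning the chosen subunit plus one subunit on either side
along the strand (a three-long-pitch-subunit window, ~165 Å) is posed
rigidly.  Three scoring choices matter and are worth stating
explicitly, because each removes a measurable bias:

* **Corridor masks.**  The mask must cover the whole azimuthal search
  arc (the mask source is fanned through the search range before
  dilation), otherwise large rotations are scored against empty space
  and the fit is dragged toward the reference azimuth.
* **Central scoring** (`score_span = "centre"`, the default): the
  correlation is evaluated over the central pseudo-repeat's
  neighbourhood only — one genetic rise to either side axially, and a
  ±8 Å radial band about the strand radius.  The flanking repeats are
  still posed (they supply the boundary density that makes terminal
  fits well-posed), but they are context, not signal; scoring the whole
  window instead (`score_span = "window"`) reports a density-weighted
  average over three repeats and systematically pulls subunits at
  state boundaries toward their neighbours by several degrees.  With
  `score_span = "window"` and a window covering the whole strand the
  fit reduces to the global one.
* **Component exclusion.**  The troponin core presses against the
  tropomyosin annulus next to subunits c and d; its density must not
  steer the rod fit.  The pipeline excludes the neighbourhood of the
  docked core positions (fanned over the plausible rotation range) from
  the scoring corridor.

Rotation from blocked is always a *difference of fits*: the same
blocked-reference segment is fitted into the Ca²⁺-treated and the
Ca²⁺-free map, and `rotation_from_blocked()` subtracts the azimuths.
Common-mode systematics cancel; noise enters twice, which the
multi-seed averaging of `parameter_recovery()` absorbs.

## Dissection

`subtract_component()` renders the docked component on the map grid at
the map's nominal resolution, scales it by a single least-squares
factor per subtraction event (`amplitude_scale()`), and subtracts.
Conservation is exact by construction: difference + s·model density
reconstructs the input to float round-off.  One scale per event is the
simplest defensible rule; sharing a scale across staged subtractions
makes them exactly equivalent to the joint subtraction (tested), and
`amplitude_scales()` provides the joint multi-component solution needed
when components overlap — the troponin core and the TnT1 tail being the
practical case: fitting them jointly and subtracting only the core
isolates the tail without eating its proximal end.

## Quantification

* **Stagger** (`troponin_stagger()`): troponin voxels are assigned to
  the nearest strand's particles, collapsed to 1D axial profiles,
  spline-upsampled to ~1 Å, and cross-correlated; the lag at the
  (parabolically interpolated) correlation maximum is the stagger.  By
  default only the globular cores are profiled — they are the compact
  features that define the stagger, while the elongated TnT1 tails
  flatten the correlation peak and admit more noise.
* **Axial span** (`axial_span()`): the extent of the axial density
  profile above a threshold fraction (default 0.2) of its maximum.
  Finite resolution widens a rod: an erf-shaped edge crosses the
  threshold `σ·qnorm(1 − f)` beyond the true end, so when the map's
  resolution is known, `2σ·qnorm(1 − f)` is subtracted.  This makes the
  measure report the underlying feature length (a 110 Å bead rod
  measures ~110 Å, not ~121 Å).  The threshold measure is stable on
  clean or lightly noisy maps; on strongly noisy single maps it is the
  least robust quantity in the package, and the acceptance measurement
  is performed on a noise-free render for that reason.
* **FSC** (`fsc()`): per-shell normalised complex correlation, shells
  one Fourier voxel wide, no masking, resolution read at the first
  threshold crossing with linear interpolation.  The default threshold
  is 0.5, the era-typical criterion for negative-stain maps (0.143
  remains available for half-map conventions).
* **State calls** (`classify_state()`): B below 9°, C from 9° to below
  23°, M at 23° and above.  The thresholds are the midpoints between
  the canonical rotations 0/18/28° — the states are named positions,
  and no published cutoffs exist — and boundary values go to the more
  activated state (a deterministic tie rule).  Both are configurable.
* **Group means** (`group_means()`): unweighted arithmetic means over
  the label groups {a,b,c} and {d,e,f,g}, pooling both strands; the
  published group means do not state a weighting, and the unweighted
  pooled mean is the natural default.
* **Residue displacement** (`residue_displacement()`): Kabsch
  least-squares superposition on an explicit frame selection —
  defaulting to all actin, the component that does not move between
  states — followed by the centroid displacement of the selection.
  The frame choice materially affects such numbers, which is why it is
  an explicit argument.  With the deposited coordinate models of the
  two states (PDB 5MVA / 5MVY, not bundled), the TnI residue-117 and
  residue-96 displacements under an actin-frame superposition are the
  published points of comparison; the synthetic tests validate the
  machinery with constructed ground truth instead.

## What the acceptance surface shows

`parameter_recovery()` regenerates mixed-state and blocked maps at
SNR 2 across seeds, runs the full pipeline on each, and reports the
recovered group rotations (truth: 28° for a–c, 18° for d–g), staggers
(truth: 27.5 Å) and TnT1 span (truth: 110 Å).  Residual per-subunit
biases of ~1–2° remain at the state boundaries (subunits c/d, and a/g
against the periodic flanks) because the generator's linear inter-repeat
interpolation makes the ground truth itself transitional there; the
group means absorb this within the stated ±2° tolerance.  These runs
use 96×96×144 maps and 20 seeds, sizes chosen so a complete recovery
study runs in minutes on a laptop core.

## Known limitations

* No flexible fitting: tropomyosin segments are rigid within a window;
  continuous strand deformation between repeat centres is represented
  only in the generator, not in the fitted model.
* No reciprocal-space or FFT-accelerated docking; searches are
  real-space grid scans sized for filament geometry.
* The noise model is white and stationary; real negative-stain noise is
  neither.
* `axial_span()` is threshold-based and inherits the fragility of
  thresholds under noise.
* Candidate-model ranking uses the same cylindrical search as the
  global fit; full 6-DoF ranking of arbitrary orientations (beyond
  axial flips expressible as azimuth/axial shifts) is out of scope.
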