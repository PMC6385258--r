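---
title: "Counting quantum-dot-labeled ligands in 3D: models and design choices"
author: "qdc3dm authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting quantum-dot-labeled ligands in 3D: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qdc3dm)
```

## The measurement problem

A cell stimulated with a growth factor such as EGF binds a discrete number
of ligand molecules, typically tens to hundreds at physiological
(picomolar-to-nanomolar) concentrations. That number varies strongly from
cell to cell, and it is the *input* of the signaling cascade — yet most
single-cell assays only observe outputs (expression, phenotype). Counting
the inputs requires single-molecule sensitivity across the full ~10 µm
thickness of a cell.

`qdc3dm` implements a calibrated counting scheme for quantum-dot (QD)
labeled ligands in wide-field 3D fluorescence stacks. The core idea is
internal calibration: the image data themselves identify which
diffraction-limited spots contain exactly one QD, those spots set the
intensity of "one molecule", and every other spot is converted to a
molecule count by division.

The three steps, run by `run_qdc3dm()`:

1. **Single-QD identification.** A high-frame-rate 2D movie is recorded in
   the QD channel. Quantum dots blink: a single emitter's 3x3-pixel trace
   alternates between a background level and one discrete "on" level. The
   trace histogram of a candidate spot is fitted with a background
   Gaussian plus a skewed-Gaussian signal peak (`classify_single_qd()`);
   spots whose histograms need more components are multiplets.
2. **Calibration.** The deconvolved 3D intensities (3 x 3 x 11 voxel
   window sums, background-subtracted) of the accepted single QDs are
   averaged into the single-molecule standard
   (`calibrate_single_qd()`).
3. **Counting.** Every detected 3D spot — including endosome-like bodies
   holding many ligands — is assigned
   `N_spot = I_spot / mean(I_single)`, and the per-cell count is the sum
   over spots (`count_cell()`).

## Mixture fitting and model selection

Trace histograms (default 100 bins) are fitted by least squares with 2–5
components: one symmetric noise Gaussian plus 1–4 signal peaks
(`fit_mixture()`). Model selection minimizes

AIC = n_bin · ln(RSS / n_bin) + 2 (3 n_Gauss − 1),

i.e. three parameters (mean, width, area) per component with one area
constrained by the total. The number of QDs in a spot is the winning
component count minus one (`count_qds_in_trace()`).

Four acceptance criteria guard against spurious fits: fit–data correlation
≥ 0.98; every component ≥ 8% of total area; pairwise component overlap
≤ 75%; and each component's area within 20% of the histogram mass on the
bins where it dominates. Two of these quantities are not uniquely defined
by their informal statements, so the package fixes them explicitly:
*overlap* is the overlap coefficient ∫ min(f_i, f_j) of the two
unit-normalized component densities, and a component's *data region* is
the set of bins where it has the largest fitted contribution
(responsibility). The single-QD classifier additionally requires that the
two levels are separated by at least σ₁ + σ₂ and that no criteria-passing
three-component model wins under AIC. These surrogate rules are
deliberately stringent: excluding a true single QD only shrinks the
calibration pool, while admitting a multiplet would bias every count in
the experiment.

The skewed signal peak is a skew-normal (location, scale, shape); the
reported component mean is the distribution mean, not the location
parameter. Least squares uses Levenberg–Marquardt with 8 seeded starts
from quantile-spaced means; the best-RSS solution is kept, and AIC ties
break toward fewer components.

## Deconvolution

The original workflow used a commercial deconvolution package (fixed PSF,
60 iterations, low noise setting). Here `richardson_lucy()` provides the
equivalent operation: multiplicative Richardson–Lucy with a fixed PSF,
reflective boundary padding, 60 iterations by default, and an optional
Tikhonov damping term for very noisy data (`damp > 0`; the default 0
matches the "low regularization" setting). Acceptance is via measurable
invariants rather than bit-equality with the commercial tool: flux of an
interior emitter is conserved to < 1%, a noiseless point source's
3 x 3 x 11 window recovers its true flux to machine precision, and
resolved spots ≥ 4 px apart do not exchange flux (each calibrates to
1 ± 0.2 QD). `psf_from_beads()` estimates the kernel from sub-diffraction
bead stacks (background-subtracted, aligned, averaged, unit-normalized);
the synthetic microscope uses a separable pixel-integrated Gaussian PSF
whose mass in any voxel window has a closed form (`psf_window_mass()`),
which is what makes the calibration arithmetic testable.

## Spot detection

2D detection (`detect_spots_2d()`) follows the
detection/estimation/deflation pattern of multiple-target tracing: a
generalized likelihood-ratio test of "Gaussian peak of known PSF width
plus flat background" against "flat background" in a sliding window,
thresholded at a per-pixel false-alarm probability (default 1e-5, exposed
in the configuration since the original report does not state its
operating point); sub-pixel refinement by nonlinear least squares; peak
subtraction and repetition until nothing exceeds threshold. 3D detection
(`detect_spots_3d()`) works on deconvolved stacks: median + k·MAD
thresholding (default k = 6), 26-connected components of ≥ 4 voxels,
intensity-weighted centroids. Large connected bodies are kept as single
spots on purpose — intensity calibration, not segmentation, resolves
their content. Spots whose 3 x 3 x 11 window would clip the stack border
(1 px laterally, 5 planes axially) are flagged and excluded from
calibration. All coordinates are 1-based array indices, the natural
convention in R; rounding to window centres is half-up, matching the
original Matlab analysis.

Background for window sums (`estimate_background()`) is the mean window
sum over regions at least 3 px from every detected spot, where the
exclusion zone is enlarged by the window half-extent per axis so that an
11-plane-deep window never touches a spot axially. Background is
estimated per stack.

## The binding simulator

Per-cell stimulation is modeled in receptor copy-number space with
constant free ligand (the extracellular volume exceeds the cellular one
by ~10^4, so depletion is negligible):

- association: rate k_on·[EGF]₀ per free receptor (pseudo-first order),
- dissociation: k_off per bound complex,
- internalization: k_int per bound complex.

`mean_bound()` solves this linear system in closed form (two-state
relaxation when k_int = 0, 2x2 eigen-decomposition otherwise);
`mean_bound_ode()` integrates the same equations numerically as an
independent cross-check, and the two agree to < 1e-8 relative on both
rate presets. Solving in copy numbers avoids committing to a conversion
volume, and is exactly equivalent to the concentration formulation under
constant ligand. Rate presets (37 °C, and a 4 °C ice-block approximation
with 100x slower association, 20x slower dissociation and no
internalization) are shipped as a YAML data file, not hard-coded.

Cell-to-cell variability enters twice. Receptor numbers follow a gamma
distribution (shape a = 3.34, mean 100,000 for the triple-negative breast
cancer line modeled here; shape is the inverse noise, scale the burst
size). Around each cell's kinetic mean, the realized bound count is
Poisson ("intrinsic noise"). `population_distribution()` computes the
resulting gamma–Poisson mixture by quadrature over 2,000 quantile-spaced
receptor nodes with Poisson support truncated at mean + 12·√mean
(truncating more than 1e-4 of mass is an error, not a silent bias);
`sample_cells()` is the seeded Monte-Carlo counterpart. At 0.03 nM EGF,
4 °C and 300 s this model predicts a coefficient of variation of ~64% —
the mixture checks out against the law of total variance to 1e-6
relative, and the CV decreases monotonically with ligand concentration
because Poisson noise shrinks relative to the receptor spread.
`percent_max_bound()` and `fit_kd()` cover the flow-cytometry isotherm
arithmetic (Langmuir fit by Levenberg–Marquardt, flagged non-identifiable
when the fitted K_D falls outside the sampled concentration range).

## Membrane geometry and internalization

The membrane is reconstructed from a stain point cloud as a 3D alpha
shape with alpha radius 50 (`build_surface()`). No installed R package
provides 3D alpha shapes, so the package carries its own incremental
Bowyer–Watson Delaunay tetrahedralization; tetrahedra with circumradius
≤ alpha are kept and their once-shared faces form the boundary surface.
A deterministic sub-resolution jitter (1e-6 of the point-cloud span)
breaks the degeneracies of cospherical inputs. The alpha radius is
interpreted in lateral-pixel units, with z rescaled by
(z-spacing / pixel size) before tetrahedralization so the shape is
computed in isotropic space — the source analysis does not state its
units, and pixel units with isotropic rescaling is the only choice that
makes a single radius meaningful in both directions.

A spot's relative radial distance ρ (`relative_distance()`) is the ratio
of nucleus-to-spot over nucleus-to-surface distance along the ray through
the spot; ρ ≤ 0.8 labels the spot internalized, and the internalized
fraction weights spots by their calibrated QD counts
(`internalized_fraction()`). When a concave surface is crossed several
times the *outermost* intersection is used, so ρ is measured against the
cell's outer envelope rather than against an invagination; on spheres the
labels agree with the analytic point-in-scaled-sphere oracle to ≥ 99%.
`register_and_project()` aligns micropatterned cells by centroid and
principal axes (180° ambiguity resolved by maximizing Jaccard mask
overlap; aligned overlap < 0.8 excludes a cell) and accumulates 2D and 1D
localization projections across cells.

## The synthetic microscope

Every pipeline stage is tested against `synthscope` ground truth rather
than real acquisitions. The generator renders point emitters under a
separable pixel-integrated Gaussian PSF, adds diffuse autofluorescence,
and applies Poisson shot noise, a gain, and Gaussian read noise. Blinking
is a per-frame two-state Markov chain; all randomness descends from one
scene seed through stage-labeled derived seeds, so identical
configuration and seed give bit-identical arrays.

Default study conditions:

- optics: 160 nm pixels, 250 nm z-spacing, PSF σ_xy = 0.7 px,
  σ_z = 1.4 planes (a 100x/1.45NA objective with near-infrared emission
  on an EMCCD), quantum efficiency 0.9, read noise 2 counts;
- 2D movies: switching rates k_on = k_off = 0.3 per frame (stationary
  on-fraction 0.5), 4000-frame traces at SNR ≥ 8 — the regime in which
  two-level traces identify single QDs;
- 3D stacks: a sticky chain with stationary on-fraction 0.9
  (k_on = 0.45, k_off = 0.05 per plane). Volumetric acquisition uses
  thick-shell QDs at low excitation and brief per-plane exposure
  precisely so that blinking perturbs 3D intensities only mildly; a 50%
  per-plane duty cycle would contradict the observed 1:2:3 quantization
  of deconvolved intensities. Dark plane runs still occur and are the
  main source of calibration dispersion (~15–20% per spot).

`generate_cell_fixture()` builds whole-cell scenes: an ellipsoidal
membrane point cloud, a central nucleus, and bound-ligand spots drawn
from the binding model, each placed internally with a specified truth
probability. What the generator does *not* emulate: power-law (heavy-
tailed) blinking kinetics, brightness heterogeneity across the QD
population, correlated on-fraction and brightness, organelle morphology,
spectral crosstalk, and dye photobleaching chemistry. Passing tests
therefore demonstrate the correctness of the calibration arithmetic and
the robustness of each stage under idealized-but-noisy imaging, not
performance on any real microscope's data.

## Numerical choices and degenerate inputs

- Histograms of constant traces produce an "unresolved" status, never an
  error; negative calibrated counts (background overshoot) clamp to zero
  with a warning.
- Mixture fits that fail to converge return a fit-failed status; the
  selection step simply skips them.
- The GLRT statistic guards zero-variance windows, and flat frames yield
  no detections by construction.
- Richardson–Lucy protects against division by zero with a machine-eps
  floor and preserves non-negativity at every iteration.
- Delaunay circumspheres of near-degenerate tetrahedra are treated as
  infinite-radius (always rejected by the alpha filter); coplanar point
  clouds are rejected with an explicit error.
- Problem sizes in the test-suite (trace counts, cells per condition,
  field sizes) are chosen as the smallest sets at which the quantities
  under test have standard errors comfortably below their tolerances,
  e.g. 10 traces per class for quantization accuracy, 52 spots for the
  1:2:3 intensity ratios, and duplicate scenes at 10/100/1000 molecules
  for count linearity.

## Known limitations

- The deconvolution stand-in cannot be validated against the commercial
  tool's output, only against physical invariants.
- The single-QD acceptance rules referenced by the original workflow are
  not public; the surrogate criteria here are documented above and tuned
  for specificity over sensitivity.
- Two-state Markov blinking underestimates the long dark periods of
  power-law blinking; QDs with heavy-tailed off-times would be rejected
  more often in step 1 (a safe failure mode) but would also widen the 3D
  intensity distribution in a way the simulator does not reproduce.
- Ligand depletion, receptor oligomerization, spatial membrane domains
  and autocrine ligand production are outside the binding model.
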