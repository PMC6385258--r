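# qdc3dm

Digital counting of quantum-dot (QD) labeled growth factors in single
cells from 3D wide-field fluorescence microscopy, for quantitative cell
biologists who need the *input* side of signaling — how many ligand
molecules each cell actually bound — rather than downstream readouts.

A cell's bound-ligand number at physiological (pM–nM) stimulation is
small, discrete, and highly variable between cells. `qdc3dm` counts it by
internal intensity calibration in three steps:

1. **Identify single QDs.** In a high-frame-rate 2D movie, a single QD's
   3×3-pixel intensity trace blinks between two discrete levels. Trace
   histograms are fitted with a background Gaussian plus skewed-Gaussian
   signal; models with 2–5 components are compared by
   `AIC = n_bin·ln(RSS/n_bin) + 2(3·n_Gauss − 1)`, and stringent criteria
   (fit correlation ≥ 0.98, component area ≥ 8%, overlap ≤ 75%,
   area-vs-data-region agreement ≤ 20%) keep multiplets out.
2. **Calibrate.** The deconvolved 3D intensities of accepted single QDs
   (3×3×11-voxel window sums, background-subtracted) are averaged into
   the single-molecule standard `mean(I_1QD_3DD)`.
3. **Count.** Every 3D spot gets `N_QD,spot = I_spot_3DD / mean(I_1QD_3DD)`,
   and `N_EGF,cell = Σ_spots N_QD,spot`.

Around that core the package provides Richardson–Lucy 3D deconvolution
with a fixed PSF, GLRT detection/estimation/deflation spot finding (2D)
and MAD-threshold connected-component detection (3D), alpha-shape
membrane reconstruction with ray-based internalization scoring
(ρ ≤ 0.8), pattern-registered 2D/1D localization projections, a
ligand–receptor binding simulator (constant-ligand kinetics,
gamma-distributed receptor numbers, Poisson intrinsic noise), and a
seeded synthetic microscope that generates ground-truthed movies, stacks
and whole-cell fixtures for every stage.

## Worked example 1: predicted stimulation distribution

How many EGF molecules does a cell with gamma-distributed EGFR numbers
(shape 3.34, mean 100,000) bind during a 5-minute 0.3 nM pulse on ice?

```r
library(qdc3dm)

params    <- kinetic_params(preset = "4C", egf0 = 0.3e-9, t = 300)
receptors <- receptor_distribution(a = 3.34, mean_NR = 1e5)

bd <- population_distribution(params, receptors)
cat(sprintf("mean bound EGF per cell: %.1f\n", bd$mean))
cat(sprintf("sd: %.1f   cv: %.0f%%\n", bd$sd, 100 * bd$cv))

sample_cells(params, receptors, n_cells = 5, seed = 1)
```

```
mean bound EGF per cell: 88.8
sd: 49.5   cv: 56%
[1]  54 143 133  89 186
```

The mean (~89 molecules) comes from the closed-form two-state solution of
the binding equations; the spread is dominated by receptor heterogeneity
with a Poisson contribution that grows in relative weight as the ligand
concentration drops.

## Worked example 2: counting molecules in a synthetic field

Sixteen emitters (thirteen single QDs, two pairs, one triple — 20 QDs in
total) are rendered into a blinking movie and a 3D stack, then counted by
the full three-step pipeline:

```r
opt <- optics_config()   # 160 nm px, 250 nm z, near-IR PSF
set.seed(5)
g  <- expand.grid(x = seq(10, 54, length.out = 4),
                  y = seq(10, 54, length.out = 4))
nq <- c(rep(1L, 13), 2L, 2L, 3L)
emitters <- lapply(1:16, function(i)
  emitter(c(g$x[i] + runif(1, -2, 2), g$y[i] + runif(1, -2, 2),
            runif(1, 14, 26)),
          n_qd = nq[i], brightness_per_qd = 2000))

field <- scene(emitters, dims = c(64, 64), autofluorescence = 20, seed = 11)
stack <- render_stack3d(field, opt, n_planes = 40)$stack
movie_emitters <- lapply(emitters, function(e) { e$brightness_per_qd <- 500; e })
movie <- render_timeseries(scene(movie_emitters, dims = c(64, 64),
                                 autofluorescence = 20, seed = 12),
                           opt, n_frames = 1500)$movie

res <- run_qdc3dm(list(seed = 3, output_dir = tempfile()),
                  movie = movie, stack = stack, psf = gaussian_psf3d(opt))
print(qdc_report(res), digits = 3)
```

```
  cell N_cell N_cell_int n_spots n_single_qd cal_mean_I cal_dispersion
1    1   19.3         19      15          12       1785            192
```

Twelve of the thirteen true singles were accepted into the calibration
(no multiplet slipped in), and the calibrated total of 19.3 recovers the
true 20 QDs. The per-spot table and a JSON summary with the full run log
are written to the output directory.

A thin command-line wrapper over the same functions is installed at
`inst/cli/qdc3dm` (`qdc3dm {simulate-binding, deconv, detect, run}`).

## Package layout

- `R/synthscope.R` — synthetic microscope and cell-fixture generator
- `R/spotdetect.R` — 2D GLRT/deflation and 3D component detection
- `R/blinkfit.R` — trace extraction, mixture fits, AIC, single-QD calls
- `R/deconv.R` — Richardson–Lucy, PSF construction/estimation
- `R/countcal.R` — window intensities, calibration, counting, AUROC
- `R/geometry.R` — alpha-shape membranes, internalization, projections
- `R/kinetics.R` — binding ODEs, gamma–Poisson mixture, isotherm fits
- `R/pipeline.R` — configuration, orchestration, reporting
- `vignettes/qdc3dm-methods.Rmd` — models, assumptions, design choices
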