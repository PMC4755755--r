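# angioquant

Quantification of tumor angiogenesis from correlated light-sheet
microscopy and MR imaging data.

Gliomas switch on rapid new-vessel recruitment as they grow, and the
shape of that vasculature — caliber, density, tortuosity, permeability —
is both a readout of disease stage and the target of antiangiogenic
therapy. Studies that track it combine light-sheet (ultra)microscopy of
optically cleared, fluorescently labeled brains (micron-scale
microvessel architecture, ex vivo) with T2\*-weighted and dynamic
contrast-enhanced (DCE) MRI (macrovessels and blood–brain-barrier
leakage, in vivo, over time). `angioquant` implements the computational
pipeline for such a study as a single tested R package:

* **Vessel morphometry** (2D planes and 3D stacks): Hessian-eigenvalue
  tubeness filtering, binarization (Otsu or fixed, threshold always
  recorded), topology-preserving skeletonization, splitting at branch
  points, a mean-minus-standard-error segment length filter, per-pixel
  radii `r_iS` from an exact Euclidean distance transform, per-segment
  means `r̄_S`, the overall mean radius `r̃ = Σ_S r̄_S / #S` (and diameter
  `2r̃`), arc/chord tortuosity of the longest decile of segments, and
  vessel density as the ROI area/volume fraction.
* **DCE permeability**: the Tofts–Kermode two-compartment model
  `C_t(t) = K_trans ∫ C_p(τ) exp(−(K_trans/v_e)(t−τ)) dτ` with a
  population biexponential arterial input function — closed-form forward
  evaluation, bounded Levenberg–Marquardt fitting of `(K_trans, v_e)`,
  voxelwise K-trans maps, and the blood–brain-barrier disruption score
  from the signal ratio `SR(t) = signal_tumor / signal_contralateral`.
* **T2\*-w vascularization**: vascularized area in mm² counting voxels
  hypointense only *after* contrast (pre-contrast hypointensities such
  as microbleeds are excluded), histogram normalization
  `(mean_tumor − mean_outside)/SD_outside`, tissue-clearing shrinkage
  factors from pre/post CT dimensions, and MR–microscopy correlation by
  ordinary least squares.
* **Synthetic phantoms** with exact ground truth: non-interpenetrating
  tortuosity-tuned tube networks rendered voxel-exactly, pre/post
  contrast volume pairs with microbleed-like dots, and simulated DCE
  series — so every stage is validated end to end by parameter recovery.

Multi-page TIFF and NIfTI I/O, YAML-driven `run_um()` / `run_dce()` /
`run_validation()` orchestration (plus a thin command-line wrapper in
`inst/cli/angioquant.R`), CSV/JSON reports.

## Worked example

Generate a 3D phantom with known geometry, quantify it, and fit
simulated contrast kinetics:

```r
library(angioquant)

spec <- phantom_spec(shape = c(96, 96, 48), pixel_size = 5, n_vessels = 6,
                     radius_range = c(10, 30), tortuosity_target = c(1.0, 1.25),
                     noise_sd = 4, seed = 7)
ph <- generate_tube_network(spec)
ph$truth
#> <phantom_truth> 6 vessels (0 branches), density 0.0429

res <- quantify_stack_3d(ph$stack, config = list(median_radius = 1))
res$report
#> <morphometry_report> 'roi'
#>   mean radius   17.373 um (diameter 34.747 um)
#>   density       0.0429
#>   tortuosity    1.1150 (longest decile)
#>   segments      5 kept / 8 total (0 loops)
#>   total length  1186.4 um

aif <- aif_biexponential(t0 = 60)
ser <- generate_dce_series(dce_sim_params(K_trans = 0.05, v_e = 0.2,
                                          noise_sd = 0.5, seed = 1), aif)
fit_tofts((ser$tumor_signal - 100) / 50, aif, ser$times_s)
#> <tofts_fit> K_trans 0.05003 /min, v_e 0.2, k_ep 0.25 /min, rss 0.0278

shrinkage_report(c(1.33, 1.05), c(0.79, 0.62))
#> <shrinkage_report> correction factor 1.689 (length 1.684, width 1.694)
#>   linear reduction 40.6% / 41.0%; ratio pre 1.267 vs post 1.274
```

Reading the numbers: the recovered mean radius (17.4 µm) sits within a
voxel of the phantom's true mean (the center-to-center radius convention
reads about half a pixel high); density matches the rendered truth
exactly; the longest-decile tortuosity 1.115 falls inside the generated
1.0–1.25 range; the noisy kinetic fit returns the simulated
K_trans = 0.05 min⁻¹ and v_e = 0.2 to a fraction of a percent; and the
pre/post clearing dimensions give the ≈1.69× size-correction factor
(≈41% linear shrinkage per axis, aspect ratio preserved).

## Layout

```
R/                  implementation (phantoms, morphometry, DCE, MR, pipeline)
src/                Rcpp core: exact EDT, 2D/3D thinning, convolution, median
tests/testthat/     unit, property and end-to-end validation tests
scripts/acceptance.R  standalone validation report
vignettes/          methods vignette (models, parameters, design choices)
inst/cli/           command-line wrapper over run_um / run_dce / run_validation
```
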