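---
title: "Quantifying glioma angiogenesis across microscopy and MR: methods and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying glioma angiogenesis across microscopy and MR: methods and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(angioquant)
```

## Scope

Brain tumors recruit new vasculature as they grow, and the morphology of
that vasculature — caliber, density, tortuosity, permeability — is both a
disease readout and a therapeutic target. Two modalities probe it at
complementary scales: light-sheet (ultra)microscopy of optically cleared
brains resolves the fluorescently labeled microvasculature at micron
resolution, while susceptibility-weighted (T2\*-w) and dynamic
contrast-enhanced (DCE) MRI track larger vessels and blood–brain-barrier
leakage in vivo, longitudinally.

`angioquant` implements the computational side of such a correlated
imaging study as one tested pipeline:

* **vessel morphometry** of microscopy stacks (tubeness filtering,
  binarization, skeletonization, branch-point splitting, per-segment
  radius, arc/chord tortuosity, vessel density), in 2D and 3D;
* **DCE pharmacokinetics** (Tofts two-compartment forward model, bounded
  least-squares fitting, voxelwise K^trans^ maps, signal-ratio
  blood–brain-barrier disruption scores);
* **T2\*-w vascularization readouts** (vascularized area with
  pre-contrast artifact exclusion, histogram normalization against healthy
  tissue) and the tissue-clearing shrinkage correction;
* a **synthetic phantom generator** that produces tube networks,
  pre/post-contrast volume pairs and contrast-kinetic series with exact
  ground truth, so every stage can be validated end to end without animal
  data.

The phantoms are the package's validation substrate, not a model of real
light-sheet optics: no deposited imaging data accompanies the protocol
this package targets, so recovery against exact synthetic truth is the
strongest check available. What passing tests demonstrate — and what they
do not — is discussed at the end.

## Vessel morphometry

### Pipeline

For a single microscopy plane the chain is: rescale to a fine working
resolution (default 0.5 µm, matching common practice of upsampling
light-sheet slices before segmentation; acquisition pixel sizes run
1.62–5.16 µm) → tubeness → binarize → skeletonize → split at branch
points → length filter → radii → summaries. For a 3D stack the chain is:
binarize → 3D median filter (radius 1) → 3D skeletonize → split →
length filter → radii, identical formulas throughout.

**Tubeness.** Curvilinear structures are enhanced with a Sato-style
Hessian eigenvalue score at a single physical scale σ (default: the
expected vessel radius). With eigenvalues sorted
|λ₁| ≤ |λ₂| (≤ |λ₃|), the score is −λ₂ in 2D when λ₂ < 0 and
√(λ₂λ₃) in 3D when both are negative, zero otherwise
(bright-on-dark polarity; a flag inverts it). Derivatives are sampled
Gaussian-derivative kernels (radius 4σ, reflect boundary), applied
separably; the second-derivative kernel is projected to zero sum so a
constant image maps to an exactly zero response. Scores are
σ²-normalized. A multi-scale maximum is available via `scales=`.

**Binarization.** The reference workflow thresholds manually per image;
for reproducibility the default here is Otsu's criterion on the pooled
histogram (via EBImage), with a fixed-threshold override, and the
threshold actually used is always recorded in the output.

**Skeletonization.** Sequential topology-preserving thinning with
directional border peeling: a voxel is deleted only if it is a simple
point (one foreground component in its 8/26-neighborhood and one
background component touching it by edge/face adjacency — the standard
simple-point characterization in 2D (8,4) and 3D (26,6) digital
topology) and not a curve endpoint (≤ 1 foreground neighbor). Candidates
per direction are re-checked at deletion time, which guarantees the
connected-component count of the mask is preserved. Like every thinning
scheme this erodes tube ends by roughly one radius; the tests budget for
that.

**Branch points and segments.** A branch point is a skeleton voxel with
more than two skeleton neighbors in the full 8/26-neighborhood. (At an
orthogonal crossing this is necessarily a small *cluster* of such voxels,
not a single pixel — diagonal adjacency between perpendicular arms is
unavoidable.) Removing branch points leaves simple paths and rings; each
is ordered end-to-end, starting from the lowest-coordinate endpoint
(lowest-coordinate voxel for a ring, which is flagged as a loop). Segment
length is the Euclidean step sum in physical units — a diagonal step
counts √2, a 3D space diagonal √3 — rather than a pixel count, which
would bias diagonal paths toward tortuosity 1.

**Centerline smoothing.** The raw digitized path systematically
overestimates arc length (up to ~8% depending on orientation, plus
thinning staircase meander), which inflates tortuosity. The quantify
pipelines therefore re-measure length and tortuosity on an
endpoint-preserving moving average of the path (window 5 points by
default, `smooth_path_window`); with windows this small the arc of a
genuinely curved vessel (radius of curvature ≫ 5 px) is essentially
untouched, while the staircase cancels. `split_segments()` itself always
reports the raw metric; window 1 disables smoothing.

**Length filter.** Very short segments are mostly cross-section stubs.
A segment is kept when its length exceeds the mean minus the standard
error (sample SD/√n) of the segment-length distribution. Reading
"standard error" as SEM rather than SD is the conventional usage but the
plain-SD variant is selectable (`length_filter_spread = "sd"`). Edge
rules: a single segment is kept; when all lengths are equal (SD = 0)
equality is retained, since the strict rule would discard everything.

**Radii.** For each centerline pixel the radius r is the minimum
distance to a non-vessel pixel, read off an exact Euclidean distance
transform (separable lower-envelope algorithm, exact for anisotropic
spacing; verified against a brute-force all-pairs scan in the tests).
The distance runs center-to-center, so a tube of geometric radius r
reads roughly r + ½ px; the reported diameter is 2r̄. This matches the
literal formula; a `half_pixel_correction` flag subtracts half a pixel
per side for users who prefer the unbiased geometric estimate (default
off).

**Summaries.** The per-segment mean radius r̄\_S is the plain average of
its pixel radii; the overall mean radius r̃ is the unweighted mean of the
r̄\_S (a mean of means — every segment counts equally regardless of pixel
count). Tortuosity is segment length over endpoint distance, averaged
over the ⌈0.1·n⌉ longest kept segments (ties broken deterministically);
loops are excluded from tortuosity but not from length or density.
Density is the vessel-voxel fraction of the ROI, a dimensionless area or
volume fraction — it is computed from the *binarized* mask, before the
3D median filter, because the median filter is a cleanup step for
thinning and would otherwise bias thin-tube densities downward. Whether
the longest-decile selection happens before or after the length filter
is not dictated by the formulas; here it is after, on the kept set.

**Shrinkage.** Solvent-based clearing shrinks brain tissue by roughly
40% in linear extent, uniformly (the pre/post length-to-width ratio is
preserved). `shrinkage_report()` turns pre/post maximum-dimension
measurements into per-axis scale factors and their mean; on the worked
CT example (1.33 × 1.05 cm before, 0.79 × 0.62 cm after) the correction
factor is ≈ 1.69 with ≈ 41% linear reduction per axis. Note an
ambiguity: per-specimen mean ratios (1.25 ± 0.01, 1.28 ± 0.03) need not
equal the ratio of mean dimensions (≈ 1.27); the report uses
ratio-of-means since only the means are available as inputs. Morphometry
reports cleared-tissue µm by default; setting `shrinkage_factor` (e.g.
1.6) in the quantify config multiplies lengths and radii back to
in-vivo scale, and is deliberately off by default so the correction is
always explicit.

## DCE pharmacokinetics

The Tofts–Kermode two-compartment model gives the tissue contrast
concentration as the exponential convolution

$$C_t(t) = K^{trans}\int_0^t C_p(\tau)\,
  e^{-(K^{trans}/v_e)(t-\tau)}\,d\tau,$$

with K^trans^ (1/min) the plasma-to-interstitium transfer constant,
v\_e the extravascular extracellular volume fraction, and
k\_ep = K^trans^/v\_e. Since no arterial input function accompanies the
protocol, the package uses the classic population biexponential plasma
decay (rates 0.144 and 0.0111 min⁻¹, amplitudes scaled to a 0.2 mmol/kg
gadodiamide dose, configurable bolus delay). For the biexponential and
impulse inputs the convolution is evaluated in closed form; a sampled
input uses an exponential recursion exact for piecewise-linear plasma
curves. Signal is converted to concentration by baseline subtraction and
a linear a.u./mM factor — the full gradient-echo signal equation needs a
baseline T1 map the acquisition does not provide, so the linear
conversion is the defensible default.

Fitting is bounded Levenberg–Marquardt (`minpack.lm`),
K^trans^ ∈ [0, 10] min⁻¹, v\_e ∈ (0, 1], from three deterministic starts,
keeping the lowest residual; the convergence flag is taken from the
optimizer's own termination code. A flat curve short-circuits to
K^trans^ = 0 with v\_e reported at its bound and flagged unidentifiable.
Rate constants are in minutes internally; every interface takes seconds.

The barrier-disruption score uses the ratio
SR(t) = signal\_tumor/signal\_contralateral and summarizes it as the time
average of SR − 1 over the post-bolus window (arbitrary units; exactly 0
when SR ≡ 1, and invariant to any common gain). How the displayed scalar
is reduced from the full 10-min series is not specified by the source
workflow; the time-averaged choice is a documented stand-in. The window
starts at the first frame whose tumor-minus-contralateral enhancement
exceeds 5 baseline SDs (first five frames), falling back to the whole
series when no onset is detectable; an explicit window overrides.

## T2\*-w vascularization readouts

Vessels fill with susceptibility contrast only after injection, whereas
microbleeds and calcifications are hypointense on both scans. The
vascularized-area operation therefore counts ROI voxels hypointense
post-contrast but *not* pre-contrast; the threshold defaults to the
outside-ROI mean − 2 SD and is always reported, and areas are in mm²
from the voxel spacing. Because one threshold drives both the inclusion
and the exclusion, the included count is monotone in the threshold only
when the pre-contrast scan has no hypointensities of its own.

Histogram normalization expresses tumor intensities in healthy-tissue
SD units: the scalar summary is (μ\_tumor − μ\_outside)/SD\_outside and the
per-voxel scores are (I\_v − μ\_outside)/SD\_outside. Both are returned —
the printed formula is a scalar but histogram figures need voxelwise
values. The outside region is the only stable SD reference, so its SD is
used. MR–microscopy agreement is summarized with ordinary least squares
(`stats::lm`); R² is the squared Pearson correlation.

## The phantom generator

The generator defines the conditions under which the pipeline is
validated:

* **Centerlines** are smoothed random walks: unit steps with fixed
  pre-drawn Gaussian direction jitter scaled by an amplitude, plus a
  5-point moving average. Because the jitter draws are held fixed, the
  realized arc/chord ratio is a deterministic, near-monotone function of
  the amplitude and is tuned by bisection — on the final, volume-clipped
  polyline — to within 2% of the per-vessel target. The truth records
  the ratio actually realized.
* **Placement** is rejection sampling, thickest vessels first. Distinct
  vessels keep a clearance of r\_i + r\_j + one voxel between
  centerlines: real vessels do not interpenetrate, and separation keeps
  the ground truth of every voxel unambiguous. Each tube must also be
  long against both the grid (≥ ¼ of the largest extent) and its own
  radius (≥ 6 r): a stub a few radii long is all end cap and carries no
  usable radius or tortuosity signal.
* **Rendering** is exact: a voxel is vessel if and only if its center
  lies within r of the finely resampled centerline (Euclidean in
  physical units, hence anisotropy-aware). The truth density is the
  rendered-mask fraction, exactly.
* **Intensities** are two-level (background/vessel) plus additive
  Gaussian noise. The contrast-based pipeline stages need nothing more;
  photon statistics and light-sheet PSFs are deliberately out of scope.
  With zero noise every output is exactly two-valued, which the tests
  exploit.
* **Pre/post-contrast pairs** render vessels hypointense only in the
  post volume and spherical 1–3 px "microbleed" dots hypointense in
  both, never overlapping a vessel (a colliding dot is re-drawn from the
  seeded stream and the relocation counted).
* **Kinetic series** drive the tumor ROI with the Tofts forward model
  and leave the contralateral ROI flat, on the protocol's 2 s / 10 min
  grid (300 frames).

All randomness flows from the integer seed in the `phantom_spec`
object; identical specification + seed reproduces every output
bit-exactly.

Defaults mirror the acquisition scales where those are stated (5.16
µm/px at 0.63x, 5 µm z-steps, 2 s DCE resolution) and plausible glioma
vessel geometry elsewhere (radii spanning 2–10 px, tortuosity 1.0–1.3
bracketing the reported healthy ≈ 1.11 and tumor ≈ 1.16 region means);
noise and contrast levels have no published reference and are chosen for
testability.

## Validation and problem sizes

`run_validation()` executes the recovery suite on compact phantoms (a
96³-scale network, a 4-point kinetic grid, the shrinkage example) in
well under a minute; the test suite additionally runs a 20-tube
160 × 160 × 80 phantom (radii 2–10 px, tortuosity targets 1.0–1.3,
noiseless and at SNR 10) and a 100-replicate SNR-20 kinetic study.
These sizes were chosen so the whole suite runs in about a minute on one
core while leaving each check statistically meaningful. Under those
conditions the pipeline recovers ≥ 90% of kept segment radii within
±1 px, region-mean tortuosity within 5% (typically < 2%), density
essentially exactly, noiseless kinetic parameters to machine precision
and noisy K^trans^ with ~1% median error. Per-segment tortuosity is
compared only for segments covering ≥ 80% of their matched vessel —
arc/chord is subadditive, so a fragment of a tortuous path is genuinely
less tortuous than the whole and a per-fragment comparison would be
ill-posed.

## Known limitations

* Radii carry the center-to-center half-pixel bias unless the correction
  flag is set; at the 0.5 µm working resolution this is ≈ 0.5 µm on the
  diameter.
* Thinning erodes tube ends by about one radius, so total path length is
  a slight underestimate and short stubs are unreliable — which is
  precisely what the length filter removes.
* The BBB-disruption scalar and the AIF are documented stand-ins;
  absolute K^trans^ values from proprietary clinical pipelines will not
  be numerically identical, though rankings and recoveries are testable
  and tested.
* Phantoms validate the measurement chain, not biology: real stacks add
  uneven illumination, labeling dropout, vessel-wall intensity profiles
  and touching vessels, all outside the generator's noise model. Results
  on real data should be checked against the recorded thresholds and the
  overlay outputs.
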