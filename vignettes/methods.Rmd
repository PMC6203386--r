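---
title: "Spatial-normalization comparison for striatal mouse PET: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial-normalization comparison for striatal mouse PET: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(petnorm)
```

# Scope

`petnorm` implements an end-to-end comparison of three spatial
normalization strategies for quantifying a striatum-enriched radioligand
in mouse brain PET: warping to an MRI template, warping to a tracer-PET
template, and rigid matching to a CT template. The pipeline is exercised
on a synthetic multimodal phantom cohort with the statistical structure
such a study assumes — inter-subject pose and shape variability,
genotype striatal atrophy, and genotype-specific binding distributions —
so that every claim the package makes can be checked against known
ground truth. This vignette documents the models, the tunable
parameters, the numerical choices, and the limits of what the synthetic
validation shows.

# Kinetic model

Regional quantification uses the simplified reference tissue model
(SRTM) with the cerebellum as reference:

$$C_T(t) = R_1\,C_R(t) + \left(k_2 - R_1 k_{2a}\right)
  \left[C_R \otimes e^{-k_{2a} t}\right](t), \qquad
  k_{2a} = \frac{k_2}{1 + BP_{ND}}.$$

* `R1` (unitless) — delivery ratio of target to reference tissue;
  phantom default 1.0 (SD 0.05 across subjects).
* `k2` (1/min) — target efflux rate; default 0.2 (SD 0.02).
* `BP_ND` (unitless) — binding potential, the outcome measure; genotype
  defaults: wild type 1.86 (SD 0.20), heterozygous 1.06 (SD 0.24),
  truncated at zero.

The convolution is evaluated on a uniform 0.1-minute grid with
piecewise-linear reference input; each step uses the interval-wise
closed form of the exponential convolution, so the quadrature is exact
for piecewise-linear curves and refining the grid to 0.02 minutes moves
`BP_ND` by less than 0.1%. The `R1` term is taken from the exact
reference samples rather than re-interpolated, which makes the algebraic
collapse (`BP_ND` = 0, `R1` = 1 implies target = reference) exact.

`srtmFit()` minimizes duration-weighted least squares
(uniform weighting selectable) by Levenberg-Marquardt from three starts,
`(R1, k2, BP) = (1, 0.1, 1), (0.8, 0.3, 0.5), (1.2, 0.05, 2)`; the
lowest residual wins, ties to the first. Bounds are `k2 > 0` and
`BP_ND > -0.99`: small negative estimates under noise are reported
rather than clipped. `bpMap()` linearizes the model over a logarithmic
grid of 100 apparent efflux rates in [0.01, 1] /min, solves the
two-parameter weighted linear fit per voxel, and then re-sweeps a fine
local grid around each voxel's selected rate — without that refinement
the grid quantization alone biases voxel `BP_ND` by ~0.3%.

The reference curve generator uses a biexponential uptake-washout shape
$C_R(t) = A(e^{-\lambda_1 t} - e^{-\lambda_2 t})$ with defaults
`A = 30 kBq/mL`, `lambda1 = 0.03 /min`, `lambda2 = 0.45 /min` (peak
near 6 minutes), a direct parametric stand-in for the cerebellar input:
SRTM needs only the reference TAC, so no arterial input model is
simulated.

# Registration

**Rigid.** `rigidRegister()` maximizes normalized mutual information
(32-bin joint histogram; normalized cross-correlation selectable and
used for same-modality pairs) with Nelder-Mead downhill simplex over the
six parameters (intrinsic z-y-x Euler angles about the fixed volume's
world center), in a two-level Gaussian smoothing pyramid. Three
numerical safeguards matter in practice:

* sampling is strided, never content-weighted — subsampling the
  background biases the joint histogram and can move the NMI optimum by
  more than a millimetre;
* the capture range is established by a coarse translation grid search
  (±2 mm) plus an axis-wise rotation sweep (±10°) before the simplex;
* the final solution is polished by a pattern search on every fixed
  voxel with a 128-bin histogram — the 32-bin metric has sub-voxel
  plateau ripples that can strand a local search a few hundredths of a
  millimetre from the optimum, which is enough to matter when a
  composed chain resamples a small VOI.

**Non-linear.** `nonlinearRegister()` parameterizes displacement per
world axis on a separable cosine basis with `cutoff` frequencies per
spatial axis (default 3, i.e. 27 basis functions per displacement
component — the package's reading of a "frequency cutoff = 3" brain
normalization; no equivalence with any commercial implementation is
claimed). The objective is variance-normalized SSD after a global
intensity rescale, plus `regWeight` times the bending energy of the
displacement field, which is diagonal in this basis (weights
proportional to the squared squared-frequency norm, normalized so the
lowest non-zero frequency has unit weight and scaled so `regWeight = 1`
is a mild penalty: strong enough to damp high frequencies in
uninformative regions, weak enough that sub-millimetre true warps
remain recoverable — the scale was fixed by requiring the inverse-crime
recovery property below). Optimization is L-BFGS with analytic
gradients, a fixed outer iteration count (default 16) per smoothing
level, over a coarse-to-fine schedule of estimation smoothings (2, 1,
0.5, 0.25 voxels); the returned objective never exceeds the identity
warp's. Displacement in image background is unidentifiable by
construction, so recovery accuracy is meaningful (and tested) inside
the head only: within-basis warps are recovered to well under 25%
residual RMS there.

Transforms compose lazily (`composeTransforms(a, b)` applies `a` then
`b`); rigid-rigid compositions collapse to a single rigid transform.
Every route resamples the dynamic data exactly once through its
composed chain — trilinear interpolation, frame-wise, with the frame
schedule preserved.

# Phantom generator

The phantom is an ellipsoidal mouse head: brain (semi-axes
3.4 x 5.2 x 2.4 mm), left/right striatum (1.1 x 1.75 x 1.0 mm each,
~16 mm^3 combined), cerebellum, and a skull shell with deliberately
asymmetric thickness plus bony landmarks (tympanic bullae, frontal
ridge) — without those asymmetries an ellipsoidal shell is nearly
rotation-invariant and skull-driven registration is ill-posed, which no
real skull is. Default grids: MRI 0.2 x 0.2 x 0.25 mm, PET 0.776 mm
isotropic, CT 0.4 mm; the reduced-scale spec (`coarsePhantomSpec()`)
keeps the same anatomy on ~0.45/0.8/0.5 mm grids for simulation studies
that must run in minutes.

Genotype effects: heterozygous striatal semi-axes are scaled by
`atrophy^(1/3)` (default atrophy 0.923, a 7.7% volume reduction of the
striatum/whole-brain ratio) with whole-brain volume untouched; true
`BP_ND` is drawn per genotype as above. Inter-subject variability
combines independent rigid poses per acquisition frame (uniform ±1 mm,
±4° — the MRI and the PET/CT sessions pose the animal independently, so
the CT-to-MRI registration has real work to do) and a smooth
low-frequency shape deformation (cosine-basis coefficients, SD 0.15 mm,
constant term excluded as it belongs to pose). These magnitudes were
chosen once as plausible for adult mice of one strain; the shape term
produces a per-subject striatum/brain ratio CV of ~6.5%, comparable to
published volumetric scatter.

MRI intensities are T2-like with deliberately subtle striatal contrast
(96 vs 100 for surrounding brain): in real T2 images the striatum is
manual-delineation territory, so non-linear normalization is driven by
brain surface and cerebellum edges, not by the structure under study.
CT soft tissue sits at 100 and skull at 1500, so the standard
threshold-at-500 skull extraction behaves as in practice. PET frames
follow the SRTM forward model per tissue (background BP_ND 0.2 for
non-striatal brain), blurred with a Gaussian PSF (default FWHM 1.5 mm,
scanner-like but not a claim about any particular scanner) and degraded
with Gaussian noise of variance proportional to activity over frame
duration — a post-reconstruction surrogate, not Poisson sinogram noise.

Ground-truth striatal volumes are measured by banded supersampled
counting: interior voxels count fully and the one-voxel boundary shell
is re-evaluated at 3x resolution per axis. Plain voxel counting carries
~1% deterministic lattice error on a 16 mm^3 structure, which would
swamp the 7.7% atrophy calibration at fixed pose. Volumetrics-only
cohorts render labels at half resolution (the supersampled boundary
keeps the accuracy) so replicate studies run in seconds per cohort.

# Templates, routes and quantification

Templates follow a single-pass, first-animal-anchored scheme: all
wild-type MRIs are normalized (rigid pre-alignment, then warp) to the
first animal's MRI, whose grid defines template space; their voxelwise
mean is the MRI template. Template VOIs are produced by majority-vote
fusion of the warped ground-truth labels — the reproducible surrogate
for manual delineation on the template. Each wild-type static PET
(duration-weighted mean over all frames) is carried through its
subject's composed chain and averaged into the tracer template; the CT
template is the first animal's thresholded CT in template space.
Registration always uses unmasked images.

Dynamic data are quantified on a PET-resolution grid anchored to the
template world frame (the first animal's PET geometry): resampling
0.776-mm PET onto a 0.2-mm MRI grid dilutes small-VOI means at region
boundaries, so quantification happens at native PET resolution with the
fused VOIs transferred once. VOI transfer across grids keeps a voxel
only when its interpolated region weight exceeds 0.75 — a conservative
membership rule that keeps transferred VOIs inside their source regions;
with a plain majority (0.5) the transferred cerebellum VOI picks up
neighboring tissue and the contaminated reference TAC biases every
downstream `BP_ND`.

The three routes mirror the study design: MRI route = (thresholded
CT -> subject MRI rigid, NMI) composed with (subject MRI -> MRI template
rigid + warp); PET route = static PET -> tracer template (rigid + warp);
CT route = thresholded CT -> CT template, rigid only. Provenance counts
the MRI route's rigid-plus-warp normalization as one estimated
transform, so the routes report 2, 1 and 1 estimated transforms
respectively. Failed registrations exclude the subject with a logged
reason rather than silently. The "individual" reference quantification
carries each subject's own labels into the PET frame through the
estimated CT-to-MRI rigid and extracts TACs from the native dynamic
data — the stand-in for manual VOIs on the individual MRI.

The focal-striatum analysis erodes the striatal VOI to 50% of its
volume at template (MRI) resolution before transfer — eroding the
few-voxel PET-resolution striatum directly would destroy it — and the
hottest-voxel analysis keeps the top 20% of striatal voxels ranked on
the tracer template, ties broken by voxel index for determinism.

# Statistics

Cohen's d uses the equal-weight pooled SD `sqrt((s1^2 + s2^2)/2)`; this
convention reproduces a consistent set of effect sizes from rounded
group summaries where (n-1)-weighted pooling does not, and the
(n-1)-weighted variant remains available. Percent differences always
carry an explicit, recorded baseline. Bland-Altman differences are
percent differences against the reference method (the MRI route in the
route comparisons), with limits of agreement at bias ± 1.96 SD.
Cross-route inference uses paired two-tailed t-tests with Bonferroni
correction (p times the number of comparisons, capped at 1); volumetric
genotype comparison uses the classic pooled-variance unpaired t-test.

# What the synthetic validation does and does not show

With noise, PSF, pose/shape jitter, atrophy and the binding spread all
disabled, the full pipeline recovers every subject's true `BP_ND` to
better than 1% and the three routes agree within 2% — the chain of
synthesis, registration, resampling, VOI transfer and fitting is
internally consistent. Each confound is then re-enabled deliberately:

* shape mismatch against the WT-built templates biases atrophied
  subjects (that is the phenomenon under study, not an estimation
  error);
* intensity-driven warping to the tracer template inflates the
  heterozygous group mean relative to the MRI route;
* rigid-only CT normalization leaves shape variability uncorrected and
  inflates both genotypes' group SDs;
* partial-volume averaging at PET resolution places measured `BP_ND`
  well below tissue-level truth everywhere (a single trilinear pass
  through an exactly known transform already costs ~8% of the striatal
  VOI mean at this striatum-to-voxel ratio).

The reduced-scale directional study (n = 8 + 8, coarse grids, noise
off, PSF on) reproduces the ordering of these effects; it does not
reproduce, and is not intended to reproduce, the magnitudes reported on
real animals, which depend on scanner physics, reconstruction and real
anatomy that the phantom deliberately simplifies. Ellipsoid anatomy,
Gaussian post-reconstruction noise, a single global deformation field
and the absence of motion, spillover from extracerebral signal, and
attenuation/scatter residuals are the main known gaps between the
phantom and real data.

# Problem sizes

Default test and acceptance runs use the reduced-scale phantom for
image-based studies (coarse grids above, 8 + 8 subjects for the
directional study, 3-4 subjects for structural checks) and the
full-resolution phantom for volumetric studies (16 + 15 subjects, 60
replicate cohorts). These sizes were chosen so a complete validation
runs on a single CPU in well under an hour while keeping every
directional claim comfortably outside its Monte-Carlo error.
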