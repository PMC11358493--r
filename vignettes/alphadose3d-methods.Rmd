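---
title: "Methods: 3D small-scale dosimetry for Ac-225 radiopharmaceuticals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D small-scale dosimetry for Ac-225 radiopharmaceuticals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alphadose3d)
```

`alphadose3d` measures where absorbed dose from an α-emitting
radiopharmaceutical actually lands inside a tumor or kidney, and what
that spatial pattern implies biologically. This vignette is the package's
own account of the models it implements, the defaults it ships, and the
limits of what its synthetic validation can show.

## The decay chain and free ²¹³Bi

²²⁵Ac (t½ = 9.9 d) decays through ²²¹Fr (4.8 min), ²¹⁷At (32 ms) and
²¹³Bi (45.6 min), which splits between direct α decay (2.1%) and β decay
to the α emitter ²¹³Po; every chain decay therefore emits four α
particles. Per primary α the emission fractions are 25% / 25% / 25% /
0.52% / 24.48%, which is how the shipped configuration
(`inst/extdata/ac225_chain.yaml`) stores them as per-chain yields
(1, 1, 1, 0.021, 0.979). α energies are standard nuclear-data values;
they are configuration, not measurement, and can be overridden.

Nuclear recoil detaches daughters from the targeting vector, and free
²¹³Bi redistributes (notably to kidney). Because ²¹³Bi is the only chain
member with a half-life between "instant" and "parent-like", the
parent/daughter pair obeys the two-nuclide relation

r(t) = (r0 − k)·exp(−(λ_b − λ_a)·t) + k,  k = λ_b/(λ_b − λ_a),

where r = A_b/A_a is the activity ratio and t is time post-sacrifice.
`ratio_at_time()` evolves it forward, `initial_daughter_activity()`
inverts it, and `fit_initial_ratio()` estimates r0 from a gamma-counting
series — the relation is linear in r0, so the fit is closed-form weighted
least squares, not an iterative optimization. The excess
A_b(0) − A_a(0) > 0 is the free-²¹³Bi activity
(`free_daughter_excess()`, clamped at zero, with a deficit flag for
blood-like tissues).

Two numerical conventions worth noting:

- k ≈ 1.0032 for this pair. It is close to, but not, 1; both behaviors
  are selectable (`equilibrium_one`) because workflows that treat
  transient equilibrium as unity exist and the difference matters only in
  the fourth decimal.
- Secular equilibrium is declared at |r − 1| < 0.05 by default, since
  measured tissue ratios like 0.97 ± 0.04 are physically equilibrium.

### The frame-coincidence factor

Frame-based α cameras merge two α events that land in the same frame.
For the ²²⁵Ac chain the culprit is ²¹⁷At: its 32 ms half-life is on the
order of a 25 fps (40 ms) frame. We model the parent decay time as
uniform within a frame and the daughter delay as exponential, giving a
same-frame probability P = 1 − (1 − e^(−λT))/(λT) and a count correction
1/(1 − P/4), one of four chain αs being at risk. At T = 40 ms and
t½ = 32 ms this evaluates to 1.09. The supplementary derivation of the
device-specific factor is not public; this is the minimal physical model
consistent with the stated mechanism, it reproduces the published value,
and the package flags it as a reconstruction (spatial-overlap effects,
if any, are not modeled). A Monte Carlo of simulated parent/daughter
pairs cross-checks P in the test suite and the acceptance script.

## Spectroscopy

Energy windows (defaults 168–268 keV for ²²¹Fr, 370–510 keV for ²¹³Bi;
175–250 / 385–490 keV for droplet calibration) are fitted with a
Gaussian photopeak on a linear background by Levenberg–Marquardt
(`minpack.lm::nls.lm`) with the area bounded below by zero.
Initialization is deliberately dumb and robust for single-peak windows:
center = window midpoint, width = window/6, area = total minus the
linear interpolation of the endpoint bins. Each window is fitted
independently — whether a shared background model across windows would
be preferable is undecidable from the published description, and
independent fits are the conservative choice. Net counts convert to
activity as `net / (branching × efficiency × live_time)`;
`calibrate_efficiency()` is the matching proportionality fit against
known-activity standards.

## The dose-point kernel

Monte Carlo particle transport is out of scope by design; the package
generates analytic continuous-slowing-down (CSDA) kernels instead, and
imports externally produced voxel kernels through the same validated
container (`load_kernel()` audits energy conservation on read). αs
travel straight isotropic tracks; the energy a yield-weighted emission
deposits in the spherical shell [r, r+dr] is the drop in its residual
energy across the shell, obtained by inverting the range–energy
relation — so the radial kernel conserves energy *by construction*, and
the shipped conservation checks (≤1%) probe only the discretization.

Stopping power in water uses a Bragg–Kleeman parameterization
(R = aE^p, p = 1.8, a calibrated to a 47.7 µm range at 6 MeV), shipped
as a plain-text table and replaceable by any measured table
(`read_stopping_power()`). For the 5.8–8.4 MeV chain αs this puts the
kernel support at ~87 µm, consistent with the sub-100 µm ranges that
motivate small-scale dosimetry in the first place. Secondary electrons
(sub-µm), recoil nuclei and β/γ are excluded; the kernel is per chain
decay under secular equilibrium.

Voxel binning averages the radial dose over a 16³ sub-voxel midpoint
grid per voxel. Two numerical choices matter:

- one octant is computed and mirrored, making the kernel bitwise
  symmetric under axis flips (an invariant the tests assert with
  `identical()`);
- the origin voxel, where dose diverges as 1/r², takes the inscribed
  sphere's energy exactly from the cumulative radial profile and samples
  only the corner remainder (40³ grid). A uniform fine grid is biased
  there no matter how fine; the exact-core split is not.

## 2D → 3D DAR dosimetry

Count images become activity images via
`counts × frame_factor / (4 × geometric_efficiency × (1 − pileup_loss)
× live_time)`, decay-corrected to sacrifice. The defaults (50%
geometric efficiency, 23.8% pileup loss) imply a 38% absolute
efficiency; both are device calibration inputs, not model outputs.

The *cloning method* approximates the unmeasured 3D neighborhood of one
measured slice by stacking copies of it — defensibly, because adjacent
10 µm cryosections are nearly identical at the ~40 µm scale the analysis
works at. The default of 21 clones at the 10 µm pitch spans ±100 µm,
containing the 87 µm kernel support. The *sequential method* (a real
stack of consecutive slices) is the reference it is validated against;
on z-uniform activity the two are identical, and the package tests that
equivalence to 1e-6. Convolution is FFT-based linear convolution with
zero padding (tissue mounted in air/OCT: escaping dose is lost), checked
against a direct double-sum oracle to 1e-8.

Sparsely sampled slices (every 200 µm) assemble into volumes whose z
voxel is pitch + slice thickness (210 µm) — each measured 10 µm slice
stands for its whole sampling interval, which is the assembly convention
recorded in the volume metadata. `sampling_plan()` does the cutting
arithmetic: a 5 mm tissue needs 500 contiguous sections, 250 for
10-slice sequential sampling at 200 µm, and 25 for cloning.

Spatial agreement is scored with the γ index (dose tolerance ×
distance-to-agreement, default 10% / 117 µm = 3 pixels, local
normalization). The search uses voxel centers (no subpixel
interpolation), restricted to a 3 × dist_tol radius by default; the
radius is configurable up to exhaustive, and the implementation is
tested against an independent all-voxel search. Published pass rates are
quoted as γ < 1; the result reports both the strict and non-strict
counts. The low-dose floor defaults to 0 (none was applied in the
validation this follows) but is configurable since 10% floors are
conventional elsewhere.

## Macro-to-micro dosimetry

A DAR is a snapshot; organ-level gamma counting provides the time axis.
Dose-rate points are fitted to A₁e^(−µ₁t) + A₂e^(−µ₂t) with non-negative
amplitudes: a Nelder–Mead search over log-rates with the amplitudes
profiled out by a two-variable non-negative least-squares step, then a
Levenberg–Marquardt polish that supplies the covariance. A
mono-exponential truth collapses cleanly to A₂ = 0. Uncertainty follows
the ±1σ parameter-modulation convention (amplitudes up / rates down for
the upper bound), which is what the bound curves and the c-factor bounds
propagate; a full covariance treatment would be possible but would not
match the bracketing the downstream bound maps are defined by.

The total dose D integrates the curve analytically to six ²²⁵Ac
half-lives (1425.6 h) — the parent governs the chain under equilibrium,
and six half-lives leave <2% of decays uncounted. Extrapolation factors
c_t = D/Ḋ(t) (units: mGy per mGy/h, i.e. hours) scale a dose-rate map
at the imaging time point into a total-dose map, assuming the spatial
distribution is frozen in time. Free-²¹³Bi dose enters as an organ-level
scalar addition (`combine_components()`): its spatial distribution is
unknown from late-imaged DARs, so pretending to voxelize it would be
false precision.

## Radiobiology

Cell survival is linear-quadratic, S = e^(−αD−βD²), with α = 1.8 Gy⁻¹
(an in vitro assay value for the targeted compound) and β = 0 by
default — for high-LET α radiation α ≫ β, and the pure-linear form is
the stated approximation; full LQ is supported. A voxel with n cells is
controlled with probability VCP = e^(−nS(D)); slices multiply voxel
VCPs and the volume multiplies slices. n is non-negative *real* (cell
densities binned to voxels), not forced integer.

The product TCP is brutally conservative: fifty slices at slice-TCP
0.95 give (0.95)⁵⁰ = 0.08 for the volume. The de-escalation calculation
therefore uses the *mean* slice TCP as its target metric (with the
volume product reported alongside), and the underdose threshold flags
voxels below VCP 0.95. Registration error at tissue edges is
de-sensitized by a 5 × 5 erosion of the n > 0 contour before the
products. De-escalation assumes dose scales linearly with injected
activity with a frozen spatial pattern; `ia_for_tcp()` bisects the
monotone TCP(IA) relation to 0.1 kBq, recomputing TCP exactly at each
trial rather than interpolating the curve.

## Morphometry

Nuclei counting is Otsu threshold → distance transform → watershed →
area filter (EBImage); the macro parameters of the original
interactive workflow are unpublished, so a relative (Otsu) threshold is
used, which also makes the count invariant to intensity rescaling.
Registration is rigid-only (translation + rotation, MSE objective,
coarse multi-start then Nelder–Mead) with the resampled image rescaled
to preserve the pixel sum — interpolation must not create or destroy
activity. Landmark-based affine refinement is interactive by nature and
out of scope; externally derived transforms can be applied through
`apply_rigid()`. Kidney compartment masks (cortex, ISOM/OSOM, IM/Pa,
V/Pe) are consumed as label images; vasculature must be pre-assigned by
the mask author, because the containment rule used in the reference
S-value comparison is anatomical judgment, not geometry the package can
infer. Combined compartments average their S values mass-unweighted
(`combine_s_regions()`), matching how the reference model combines
ISOM/OSOM and IM/Pa.

## What the phantoms emulate — and what they do not

The generators produce every input the pipeline consumes, bit-reproducible
under a seed (all simulators draw from a local RNG and restore the global
stream):

- **Tumor:** ellipsoid with a necrotic core realizing the requested
  volume fraction (core semi-axes scale as the cube root), low core uptake
  (0.1 relative) and cell density (10 cells/voxel) against a viable rim
  (uptake 1, 500 cells/voxel). The densities are synthetic, chosen so
  TCP transitions fall inside the 0–18.5 kBq range used in de-escalation
  demonstrations.
- **Kidney:** concentric compartments plus a vasculature/pelvis wedge
  with relative uptakes (1, 0.50, 0.88, 1.19) — measured 24 h
  compartment dose-rate ratios — realized *exactly* before noise.
- **Measurements:** Poisson counts through the full calibration chain,
  Poisson spectra, multiplicative-noise ratio series, and lognormal
  inter-subject scaling of a shared bi-exponential (CV 30% by default, a
  synthetic stand-in for the dominant uncertainty in small cohorts;
  lognormal for positivity).

They deliberately do not emulate: anatomical microstructure (tubules,
glomeruli — the cloning assumption is expected to fail at that scale),
slice damage and folding, registration mismatch between modalities,
device flat-field structure, or kinetics that change spatial pattern
over time. Passing the end-to-end recovery tests therefore shows the
*computational chain* is unbiased under its own assumptions — it does
not validate those assumptions on real tissue, which is what the
sequential-vs-cloning and γ machinery is for when real stacks exist.

## Problem sizes and numerical defaults

The shipped tests and demo pipeline run at desk scale, chosen as the
smallest geometries that keep the physics honest: tumor phantoms of
24 × 24 × 81 voxels at 39 × 39 × 10 µm (the z extent spans ~9 kernel
supports, so cloning's founding assumption holds away from the poles),
kernels at 0.5 µm radial step binned with 16³ supersampling, 200-replicate
recovery studies, and a 10⁶-pair Monte Carlo for the frame factor.
Convolution accuracy is independent of scale (FFT, checked at 1e-8
against direct summation), so larger real datasets change runtime, not
correctness.

Other defaults: float64 everywhere in R (images are stored as 32-bit
TIFF with a power-of-two scale and an integer flag, so count images
round-trip exactly); all internal times in seconds with explicit unit
suffixes at the configuration boundary; 0-based voxel-center geometry
with z equal to cut order.

## Known limitations

- The frame-coincidence model is a reconstruction of a device-specific
  derivation; it matches the published value at the published operating
  point but has not been validated against list-mode data.
- The CSDA kernel ignores straggling, scattering and tissue
  heterogeneity; for ~40 µm voxels these are second-order against the
  calibration uncertainties, but a Monte Carlo kernel can be dropped in
  via `load_kernel()`.
- Bound propagation combines fit bounds only; DAR counting noise is not
  folded into the per-voxel dose bounds.
- TCP ignores hypoxia, repopulation, repair and variable
  radiosensitivity, and the product form is knife-edge by construction;
  treat absolute TCP values as a ranking tool, not a clinical predictor.
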