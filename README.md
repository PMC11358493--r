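# alphadose3d

Small-scale (sub-organ, sub-tumor) absorbed-dose analysis for ²²⁵Ac
radiopharmaceutical therapy, built around quantitative α-particle digital
autoradiography (DAR).

α-emitting ²²⁵Ac compounds deliver dose over ranges below 100 µm, far
under the resolution of PET/SPECT, so dose heterogeneity inside a tumor or
kidney — and its biological consequence — can only be measured ex vivo on
thin tissue sections. `alphadose3d` implements the full analysis chain
that turns single-α-event count images into 3D dose volumes and biological
endpoints:

- **Decay-chain kinetics.** The ²²⁵Ac → ²²¹Fr → ²¹⁷At → ²¹³Bi/²¹³Po chain,
  with the two-nuclide activity-ratio relation
  `A_b(t)/A_a(t) = (A_b(0)/A_a(0) − k) e^{−(λ_b−λ_a)t} + k`,
  `k = λ_b/(λ_b−λ_a)`, used to quantify free (recoil-redistributed) ²¹³Bi
  from post-sacrifice gamma counting, and a frame-coincidence correction
  for α cameras (1.09 at 40 ms frames for the 32 ms ²¹⁷At daughter).
- **Spectroscopy.** Gaussian-plus-linear-background energy-window fits for
  the ²²¹Fr (168–268 keV) and ²¹³Bi (370–510 keV) windows, branching /
  efficiency corrections, and known-activity efficiency calibration.
- **Dose-point kernels.** Analytic continuous-slowing-down (CSDA) radial
  kernels for the chain's α emissions in water (Gy per chain decay),
  binned to anisotropic DAR voxels (e.g. 39 × 39 × 10 µm) with exact
  flip symmetry and ≤1% energy-conservation error.
- **2D → 3D DAR dosimetry.** Calibrated activity images
  (`counts → Bq` via geometric efficiency × pileup × frame factor), the
  *cloning method* (duplicate one measured slice into the convolution
  volume), the sequential reference method, sparse-sampling 3D assembly
  (200 µm pitch → 39 × 39 × 210 µm voxels), and γ-index validation
  (default 10% / 117 µm, local normalization).
- **Macro-to-micro kinetics.** Bi-exponential time–dose-rate fits with
  ±1σ bound curves, analytic integration to six ²²⁵Ac half-lives, and
  extrapolation factors `c_t = D / Ḋ(t)` that scale a dose-rate snapshot
  to total voxel dose.
- **Radiobiology.** Linear-quadratic survival `S = e^{−αD−βD²}`
  (α = 1.8 Gy⁻¹ default, β = 0), voxel control probability
  `VCP = e^{−n S(D)}`, slice/volume TCP products, and injected-activity
  de-escalation curves with bisection to a target TCP.
- **Morphometry.** Watershed nuclei counting from H&E-like images, rigid
  MSE registration with pixel-sum preservation, 5 × 5 edge erosion,
  per-compartment dose-rate–volume histograms (DrVH), and regional
  S-value dosimetry.
- **Phantoms.** Seeded synthetic tumors (necrotic core + viable rim) and
  four-compartment kidneys, plus Poisson count, spectrum, ratio-series and
  biodistribution-cohort simulators, so the whole pipeline runs and is
  validated without any animal data.

Tabular results are tibbles with `tidy()`/`glance()`/`autoplot()`
methods; images and volumes are plain numeric arrays with explicit voxel
metadata.

## Worked example

```r
library(alphadose3d)
chain <- ac225_chain()
frame_coincidence_factor(0.040, 0.032, 4)
#> [1] 1.090247

kernel <- bin_kernel_to_voxels(generate_csda_kernel(chain), c(39, 39, 10))
kernel$support_radius_um       # max alpha range in water, um
#> [1] 86.95678

# phantom slice -> simulated counts -> calibrated activity -> dose rate
ph  <- tumor_phantom(phantom_spec(shape = c(24, 24, 41),
                                  voxel_dims_um = c(39, 39, 10),
                                  total_activity_Bq = 1.5, seed = 1))
cal <- calibration_factors()    # 50% geometric, 23.8% pileup, 1.09 frame
slice  <- activity_image(ph$activity$activity[, , 21], 39, 10)
counts <- simulate_counts(slice, cal, live_time = 86400, chain, seed = 1)
dr <- cloning_dose_rate(counts_to_activity_image(counts, cal, chain),
                        kernel, n_clones = 21)
mean(dr$dose_rate) * 1000       # mGy/h
#> [1] 100.4111

# macro-to-micro: cohort fit, extrapolation factor, total dose, TCP
cohort <- simulate_biod_cohort(list(amplitudes = c(60, 15),
                                    rates = c(0.08, 0.003)),
                               c(24, 48, 96, 168), 17, 0.3, seed = 2)
fit <- fit_biexponential(cohort)
cf  <- extrapolation_factor(fit, 24)
cf[, c("total_dose_mGy", "rate_mGy_h", "c")]
#> # A tibble: 1 × 3
#>   total_dose_mGy rate_mGy_h     c
#>            <dbl>      <dbl> <dbl>
#> 1          5968.       23.9  250.

dose <- scale_dose_map(dr, cf)
glance(tcp(dose$dose, ph$cells[, , 21], radiosensitivity(alpha = 1.8)))
#> # A tibble: 1 × 5
#>   volume_tcp mean_slice_tcp min_slice_tcp n_slices n_underdosed
#>        <dbl>          <dbl>         <dbl>    <int>        <int>
#> 1      0.999          0.999         0.999        1            0
```

The numbers read: the slice receives ~100 mGy/h at 24 h; the fitted
time–dose-rate curve integrates to ~6 Gy per unit uptake with a 24-h
extrapolation factor of ~250 h; and at the resulting voxel doses the
slice is essentially fully controlled (TCP ≈ 1).

`run_pipeline(pipeline_config(seed = 1))` executes the entire chain
(phantom → counts → calibration → cloning dose rates → 3D assembly →
kinetics → TCP → DrVH → γ validation → de-escalation) and returns a
structured report; `run_pipeline(cfg, out = "report.json")` writes it as
JSON.

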