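---
title: "Methods: volumetric quantification and response modeling of optogenetic signaling activation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: volumetric quantification and response modeling of optogenetic signaling activation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(optoquant)
```

# The measurement problem

Blue-light optogenetic activators (LOV-domain receptor kinase fusions for
the FGF, BMP, and Nodal pathways) are delivered to zebrafish embryos as
injected mRNA, which distributes mosaically. The activity readout is a
phospho-effector immunofluorescence signal (ppERK, pSmad1, pSmad2) imaged
as a confocal z-stack together with a nuclear stain (DAPI) and a co-injected
GFP reporter that proxies where the construct actually is. Two confounders
dominate: heterogeneous construct levels (addressed by voxelwise GFP
normalization) and baseline pathway activity (addressed by subtracting a
matched dark control). What remains is a dark-subtracted, GFP-normalized
signal whose dependence on exposure time or irradiance is the quantity of
scientific interest.

# Quantification model

For each sample the pipeline builds three 3D masks by intensity
thresholding: the nuclear **DAPI region**, the reporter-positive **GFP
region**, and their voxelwise intersection, the **DAPI+GFP region**. Mask
membership is *strict* (`intensity > threshold`); the comparison direction
has to be fixed for the algebra of masks to be well defined (a threshold at
the global maximum yields an empty mask). The effector channel is divided
voxelwise by the GFP channel; voxels with zero reporter signal are marked
undefined and excluded from all downstream medians rather than clamped with
an epsilon — any epsilon would silently distort a median whose inputs span
orders of magnitude. Six medians summarize the sample: raw and
GFP-normalized effector signal within each of the three regions, computed
over the full 3D volume (not a projection), with the even-count median
defined as the mean of the two central order statistics. An empty region or
an all-undefined region yields a missing value plus a QC reason, never a
silent zero.

Downstream analyses consume one statistic per sample according to the
pathway rule: FGF and BMP read the GFP-normalized median within the GFP
region; Nodal, whose effector is largely nuclear, reads the DAPI+GFP
region. The rule is a config default (`run_config()`), overridable.

Thresholds default to Otsu's method — the split maximizing between-class
variance, computed exactly over unique intensity values (binned to 256
levels for near-continuous data) — standing in reproducibly for the
user-prompted thresholding of interactive workflows; manual thresholds are
accepted unchanged.

## Quality control

Three criteria are automatable and implemented; the rest are visual and
pass through as manual flags in the manifest (off-frame, second embryo,
mounting angle above ~40 degrees, truncated stack):

- **Reporter coverage**: the sample fails when less than 5% of the embryo
  extent is covered by the GFP mask (too little construct to analyze). The
  embryo extent — which the 5% refers to — is the largest 6-connected
  component of the DAPI channel above a low background threshold found by
  two-stage Otsu (first split isolates bright nuclei; a second Otsu on the
  sub-nuclear intensities separates diffuse intra-embryo signal from the
  featureless background).
- **Saturation streaking** is inherently a visual call; the automated
  stand-in flags any channel whose fraction of voxels at the bit-depth
  maximum exceeds 1% (configurable). This is a heuristic and is documented
  as such.
- **Nuclear-channel damage**: the sample fails when an enclosed
  below-background void (a connected component of sub-threshold voxels not
  touching the volume border — the fill-holes definition) spans at least a
  third of the embryo extent. A void that large necessarily has the
  geometry of a hollowed interior with a thin surviving shell; surface
  defects connected to the outside background are intentionally not counted,
  since they are indistinguishable from embryo shape.

Saturated voxels inside a sample that passes QC are retained in the
medians; the streaking gate, not the median, is the guard against them.

# Response model

The dark-subtracted normalized signal `y` against time `x` (min) or
irradiance `x` (W/m²) is fit by the three-parameter logistic

$$y = \frac{c}{1 + e^{-a (x - b)}}$$

with growth rate `a` (per min or per W/m²), inflection `b` (min or W/m²),
and upper asymptote `c` (AU); the lower asymptote is fixed at zero on the
assumption that dark-subtracted signal starts at (on) or returns to (off)
baseline. `c` is constrained non-negative; `a` is negative for the off
phase, whose time axis is re-expressed as time since light removal (the
exposure end, 30 min by default, is explicit in the configuration).
Negative `y` values — dark subtraction can undershoot — are retained, not
clipped.

**Fitting.** Deterministic multi-start Levenberg-Marquardt
(`minpack.lm::nlsLM` under the hood): `c0 = max(y)`, `b0` the sampled `x`
nearest the half-maximum crossing, and `a0` over the fixed grid
{0.05, 0.5, 5} (sign-filtered by direction and additionally rescaled by
10/range(x), so time courses spanning tens of minutes and irradiance
ladders spanning decades both receive useful starts); the lowest-SSE
candidate wins, making fits reproducible without a random initializer.
Constant-zero data degenerate to `c = 0` and are flagged rather than
erroring; non-convergence returns the best candidate with
`converged = FALSE`, never silently. Goodness of fit is
`R² = 1 − SS_res/SS_tot`.

**Derived parameters.** Inverting the fit gives the conventional summary
quantiles: for a rise, the time (or irradiance) to reach fraction `p` of
the asymptote is `x_p = b − a⁻¹ log((1−p)/p)` (tON_20 initial activation,
tON_50 half-maximum, tON_90 saturation; I_20/I_50/I_90 on the irradiance
axis); for a decay, the time from light removal to *lose* fraction `p` is
`x_p = b − a⁻¹ log(p/(1−p))`. At `p = 0.5` both reduce to `b` exactly — an
analytic identity the test suite enforces to 1e-9. Derived times below zero
are legitimate (a shallow curve can place its 20% crossing before time
zero) and are reported as-is.

**Uncertainty.** The upstream analysis this mirrors reports 95% CIs without
stating a method, so the method here is a package choice: a seeded residual
bootstrap (resample residuals onto fitted values, refit from the original
estimates, recompute the derived quantity; percentile 2.5/97.5 bounds;
intervals flagged unreliable when more than 20% of refits fail). First-order
delta-method intervals are exposed alongside for comparison
(`derived_ci(..., method = "delta")`). Numeric CI values therefore need not
match any particular external software's intervals. Parameter CIs for
`a`, `b`, `c` are Wald intervals from the fit covariance.

**Replicate handling.** Technical replicates (embryos) are averaged within
condition and biological replicate; fits default to the per-time-point
replicate means (`fit_scope = "replicate_mean"`), matching the aggregation
that produces one value per replicate and time, with pooled per-replicate
fitting available as an option.

# Group statistics

Wavelength comparisons use a REML random-intercept model
(`value ~ condition + (1 | replicate)`) with predicted least-square means
and an F-test of the condition effect. Standard mixed-model machinery is
the right tool here, so the model is fit by `lme4`/`lmerTest` with
`emmeans` for the marginal means; the package's own contribution is the
surrounding contract, and the test suite cross-checks the REML estimates
against an independent profiled-likelihood grid computed from dense
matrices. On balanced designs least-square means equal arithmetic group
means exactly — also enforced by test.

Kinetics time-courses are additionally screened by one-way ANOVA with a
fixed effect of time, followed (when the effect is significant) by Dunnett
comparisons of each time point against time = 0. Multiple-comparison
adjustment — Dunnett versus-control and Tukey all-pairs — is by seeded
Monte-Carlo simulation of the null max-|t| distribution for the actual
design (shared-control correlation included; 1e5 draws by default). The
Monte-Carlo route keeps the machinery transparent and testable: a two-group
Dunnett must agree with the plain t-test, and the simulated k = 3
family-wise error must sit at 5%. Adjusted p-values are clamped to be at
least the unadjusted p, so the dominance invariant holds exactly despite
Monte-Carlo noise.

The phenotype-based inclusion gate encodes the mRNA-quality rules on 1 dpf
phenotype counts: FGF/Nodal experiments proceed iff at least 60% of
injected light-exposed embryos are severely deformed or lysed; BMP iff at
least 60% show V1–V4 ventralization with V2-or-higher present; any
experiment fails on more than 20% disallowed phenotypes in the
dark-injected condition, and is excluded outright when uninjected embryos
show over 30% defects in both dark and light. Boundary ties follow the
wording: exactly 60% passes ("at least"), exactly 20% passes ("more
than" fails).

# Photometry

All internal arithmetic is SI: irradiance is measured power divided by the
detector (or scanned-ROI) area, dosage is irradiance x duration (J/m²).
µW, mm², µm², and minutes are converted explicitly at the boundary because
published exposure protocols mix all of them. For scanned-ROI activation
the effective irradiance is the time-averaged power over the ROI area,
optionally scaled by a dwell (duty) fraction. Reported ROI irradiances in
the protocol this mirrors (126.93 and 47.60 W/m²) are not exactly
reproducible from the printed rounded inputs (5.6 and 2.1 µW over
45,000 µm² give 124.44 and 46.67 W/m² by plain division — the printed
values imply unrounded power readings); the package always reports its own
arithmetic from the inputs given. The dosage identity
47.60 W/m² × 300 s = 14280.00 J/m² is exact and serves as the worked
example.

# The synthetic embryo generator

The generator exists to give every pipeline stage a ground truth. It is
deliberately a *statistical* stand-in, not an optics simulation:

- **Geometry**: a hemispherical cap of cells (animal pole up, z = 1 at the
  stack top) on a featureless background; nuclei are non-overlapping
  spheres placed by rejection sampling. This is sufficient to exercise
  masking, median, coverage, and connectivity logic; it does not model cell
  shape, movement, or layering.
- **Mosaic reporter**: a sum of Gaussian bumps at random in-embryo centers,
  thresholded at the quantile that yields a requested coverage fraction —
  clonal patches with controllable scale (`patch_scale_um`, default 40 µm)
  and exact coverage, which the QC tests exploit (3% vs 7% against the 5%
  rule).
- **Signal model**: expected effector intensity is
  `baseline + gain × activation × reporter`, restricted to nuclei for
  nuclear effectors and to an ROI box for spatial-activation emulation;
  additive Gaussian noise, clipping at the saturation ceiling, and rounding
  to integer counts. Choosing `effector_gain = c_true` makes the full image
  pipeline reproduce the programmed response parameters in original units.
- **Determinism**: every output is a pure function of the truth object and
  its seed; dataset samples derive per-sample seeds from the base seed.

Default grid 64x128x128 at a 9 µm z-step mirrors the stack spacing of the
motivating experiments while staying desk-scale; tests and the acceptance
script use smaller grids (12x24x24 to 16x48x48, embryo radius 55–120 µm,
25–120 nuclei) chosen so the whole validation suite runs in minutes on one
CPU. Response-level simulation studies use the 11-point fixation ladder
with 3 replicates and noise at 10% of the asymptote — the design scale of
the experiments being emulated — with 200 simulated datasets and 500
bootstrap replicates per interval.

What passing tests on synthetic data do **not** show: robustness to PSF
blur, scattering-induced depth attenuation, the light-cone artifact of
scanned illumination, segmentation behavior on touching nuclei, or
embryo-to-embryo variance structure (no published variance magnitudes
exist to calibrate against, so between-embryo variability is exposed as
free parameters rather than asserted).

# Numerical and design choices

- Strict `>` mask membership; division-by-zero exclusion; 3D medians —
  all discussed above.
- Connected components (embryo extent, damage voids) use 6-connectivity via
  a graph-components algorithm on the foreground voxel adjacency.
- Volumes are stored as plain multi-page TIFF (channel-major pages) with a
  JSON sidecar for channel names, voxel size, and bit depth; integer 8/16
  bit data round-trip losslessly. Proprietary microscope formats are out of
  scope.
- Dunnett/Tukey critical values by seeded Monte Carlo rather than
  multivariate-t quadrature — transparent, dependency-light, and directly
  testable against the two-group t oracle.
- The bootstrap seed, Monte-Carlo seeds, and generator seeds are all
  explicit arguments; a fixed seed makes every end-to-end run bit
  reproducible.
- With only three biological replicate levels, the between-replicate
  variance estimator is approximately chi-squared with 2 degrees of
  freedom: its *median* across repeated experiments sits about a third
  below the true component even though the estimator is unbiased in mean.
  Validation therefore summarizes the replicate component by its mean and
  the residual component by its median.

# Known limitations

- Masks are purely threshold-based; there is no nucleus instance
  segmentation, tracking, or registration.
- The saturation-streak detector is a proxy for a visual judgment and will
  miss structured streaks that saturate few voxels.
- Only the three-parameter logistic is offered; alternative response shapes
  (free-exponent Hill, biexponential decay) are intentionally out of scope.
- Bootstrap CIs inherit the usual small-sample caveats when the fit is
  near-degenerate (flat curves, asymptote outside the sampled range); the
  `reliable` flag and the degenerate-fit flag surface these cases instead
  of hiding them.
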