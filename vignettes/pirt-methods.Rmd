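---
title: "Modelling hypoxia-modulated radiotherapy response in glioma: methods and design"
author: "pirt package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling hypoxia-modulated radiotherapy response in glioma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

Glioblastoma is diffusely invasive: malignant cells infiltrate centimetres
beyond the abnormality visible on MRI, so any model of its growth and
treatment response has to describe a *density field*, not a lesion boundary.
`pirt` implements the proliferation-invasion model with a radiotherapy loss
term. The tumour cell density $c(\mathbf{x}, t)$ (cells/mm^3^) on a voxelised
brain obeys

$$\frac{\partial c}{\partial t} =
  \nabla \cdot \big( D(\mathbf{x}) \nabla c \big)
  + \rho\, c \left( 1 - \frac{c}{K} \right)
  - R(\mathbf{x}, t)\, c \left( 1 - \frac{c}{K} \right),$$

with no-flux conditions wherever brain parenchyma meets CSF or the skull.
The three terms are:

* **Invasion.** $D(\mathbf{x})$ (mm^2^/year) is built from a tissue
  composition map: glioma cells migrate along myelinated white-matter tracts
  about 100 times faster than through grey matter, $D_w = 100\,D_g$, and not
  at all through CSF. For partial-volume voxels we blend linearly,
  $D = D_w f_w + D_g f_g$, and a voxel belongs to the simulation domain when
  $f_g + f_w > 0.5$ (`buildDiffusionMap()`). Whether a published net invasion
  rate refers to the white- or grey-matter rate is often ambiguous; the
  builder takes it as $D_w$ by default with a `dIsWhite` switch.

* **Logistic proliferation.** $\rho$ (1/year) is the net proliferation rate
  and $K$ the tissue carrying capacity. With a nominal 10 µm cell diameter,
  $K = 1/\left(\tfrac{4}{3}\pi (d/2)^3\right) = 1.91\times10^6$ cells/mm^3^
  (`carryingCapacity()`); at $c = K$ proliferation stops, which we read as a
  quiescent/necrotic core.

* **Radiotherapy.** Each fraction is an instantaneous, deterministic event.
  The surviving fraction comes from the linear-quadratic model,
  $S = \exp(-\alpha d - \beta d^2)$ with $\alpha/\beta$ fixed at 10 Gy for
  tumour tissue, leaving $\alpha$ (1/Gy) as the single patient-specific
  radiosensitivity parameter. The kill is density-dependent,
  $c \mapsto c - (1 - S)\, c\,(1 - c/K)$: fully effective on sparse,
  proliferating cells, and exactly zero at carrying capacity, where the
  tissue is modelled as already dead. First-order sublethal-damage repair is
  deliberately not modelled; it is negligible at fraction doses below 2 Gy.

## Hypoxia as spatial radioresistance

Hypoxic cells are radioresistant. An FMISO-PET image, scaled voxel-wise by
the mean venous blood activity into a tumour/blood (T/B) ratio
(`computeTB()`), delineates hypoxia: voxels with T/B ≥ 1.2 (inclusive),
restricted to the tumour region (by convention the T2 abnormality plus a
2 cm margin, which suppresses scattered PET noise elsewhere), form the
hypoxic volume HV (`hypoxicVolume()`). Inside HV the radiobiological
parameters are divided by an oxygen enhancement ratio,
$\alpha \to \alpha/\mathrm{OER}$, $\beta \to \beta/\mathrm{OER}^2$, with
OER ∈ [1, 3] applied binarily per voxel (`buildOERMap()`). This is
algebraically identical to reducing the local dose by the OER factor, an
identity the test suite checks to machine precision. Intravoxel heterogeneity
of oxygenation and re-oxygenation during the treatment course are outside the
model: the OER map is static.

## Dose plans

`buildConformalPlan()` produces the standard two-phase prescription: 54 Gy in
30 daily 1.8 Gy fractions to the T2 abnormality dilated by 2.5 cm, then a
sequential boost of 7.2 Gy in 4 fractions to the T1Gd abnormality dilated by
2 cm, 61.2 Gy total in the boost region. Margins are Euclidean-ball dilations
(`dilateMask()`, FFT convolution with the ball indicator — exact for binary
masks). The dose is an idealised step function with no penumbra gradient;
arbitrary per-fraction dose grids can be supplied through
`dosePlanFromGrid()` instead. Fractions fall on consecutive weekdays (day 0
is a Monday by convention); strictly consecutive days are available via
`weekdaysOnly = FALSE`.

# Numerics

The solver (`simulateGrowth()`) uses:

* **Flux-form central differences** for $\nabla\cdot(D\nabla c)$ with
  face-averaged diffusivities, zeroed across any face touching an off-domain
  voxel. Flux form makes the scheme discretely conservative: with $\rho = 0$
  total cell number is conserved to round-off (the suite demands < 10^-6^
  relative drift over > 1000 steps).
* **Strang splitting** with an *exact* logistic substep
  ($c \mapsto K c e^{\rho h}/(K + c(e^{\rho h} - 1))$) on each half-step.
  With $D = 0$ the solution therefore matches the logistic closed form to
  round-off, and the splitting is second-order in the step, so halving the
  step changes the final burden by well under 0.5 %.
* **Stability bound** $\Delta t \le 0.9\, \min(dx)^2 / (2\, n_{dim} \max D)$
  jointly with $\Delta t \le 0.1/\rho$, in days (rates per year are divided
  by 365; the internal clock is days because fraction schedules are daily).
  A user-supplied coarser step is refined automatically by default, or
  rejected with `autoRefine = FALSE`.
* **Event alignment**: integration lands exactly on every fraction day and
  requested output time; the kill event is applied after the step reaching
  it. Negative densities from round-off are clamped to zero and the clamped
  mass is reported in the `SimulationResult`.

A spherically symmetric finite-volume solver on concentric shells
(`simulateRadial()`, `runSpherical()`) provides the anatomically simplified
variant — used both for the scenario where the hypoxic region is proxied by
the bulk-tumour (T1Gd) isodensity instead of a PET image, and as an
independent numerical cross-check: on a homogeneous spherical problem the 1D
and 3D solvers agree on total cell count to within 2 %.

# From images to parameters

## Observations

Tumour volumes follow the clinical slice-summation convention
$V = \sum_i A_i\, dz_i$ (`volumeFromMask()`), and sizes are compared through
the radius of the sphere of equivalent volume (`equivalentRadius()`). A
simulated density field becomes a virtual MRI observation by thresholding at
a detection density: 0.80 K for the contrast-enhancing T1Gd abnormality and
0.16 K for the T2/FLAIR abnormality (`virtualMRI()`). These thresholds are
the values used across the proliferation-invasion modelling literature but
are not printed in every study; they are package defaults, prominently
configurable everywhere they enter (`detectionThresholds()`).

## Estimating D and rho

Two pre-treatment MRI pairs give two numbers: the radial growth velocity of
the bulk tumour between the dates (annualised, cm/year; `growthVelocity()`),
which the model equates with the Fisher front speed $v = 2\sqrt{D\rho}$, and
the T1Gd–T2 radius gap, which measures the infiltration width
$\lambda = \sqrt{D/\rho}$ (the square root of the "invisibility index"
$D/\rho$). `estimateDRho()` inverts the pair so that both identities hold
exactly.

The one genuinely open choice is the constant converting the radius gap into
$\lambda$. Placing both thresholds on the exponential far tail
$c \propto e^{-r/\lambda}$ gives $\mathrm{gap} = \lambda \ln(0.80/0.16)
\approx 1.61\lambda$. But 0.16 K and 0.80 K do not sit in the far tail: they
sit on the travelling-wave interface itself. Integrating the minimal-speed
wave profile (in scaled units $U'' + 2U' + U(1-U) = 0$) shows the
0.80→0.16 crossing distance is ≈ 6.1 λ (`fisherWaveGap()`), and
grid-refined 1D simulations of the solver reproduce that width. The package
therefore defaults to the wave-consistent conversion — with it, parameters
estimated from simulated tumours round-trip to the generating values (the
suite requires 20 %, and both rates come back within ~6 % at 1 mm
resolution) — while `profile = "exponential-tail"` selects the tail
convention, since published parameter sets differ by exactly such O(1)
factors. Estimates are reported (`PatientParameters`) with both the supplied
velocity and the $2\sqrt{D\rho}$ it implies; when the two disagree (as
published tables sometimes do) they are printed side by side, never silently
reconciled.

## Calibrating alpha

With $(D, \rho)$ fixed and $\alpha/\beta$ pinned at 10 Gy, the simulated
post-treatment size is strictly decreasing in $\alpha$, so the size–response
relationship is one-to-one. `calibrateAlpha()` exploits that monotonicity
with a deterministic bracketed bisection on the radius residual (bracket
$[10^{-4}, 0.5]$ Gy^-1^, default radius tolerance 10^-3^ mm against the first
post-treatment T2 size). Observed sizes outside the achievable range return
the nearer bracket endpoint, flagged and with a warning, rather than a
spurious interior optimum. On self-generated patients the ground-truth
$\alpha$ is recovered to well within 10 %.

# The synthetic cohort

Real inputs (MRI segmentations, a planning-system dose grid, an FMISO-PET
study) are rarely shareable, so the generators in `makePhantom()`,
`makeTBMap()` and `makeVirtualPatient()` produce every input the pipeline
reads, deterministically from a seed.

**Head phantom.** An ellipsoidal head (semi-axes 0.92 of the half grid
extent) with a grey-matter shell, white interior and two ellipsoidal CSF
ventricles, blended fractionally over a one-voxel ramp at every interface.
The default shell is 7 mm thick — intentionally thicker than a cortical
ribbon — so that grey matter is ~40 % of brain volume, as it is in real
brains where deep grey nuclei add to the cortex; the grey fraction matters
quantitatively for the T/B generator below.

**T/B image.** The whole-brain T/B histogram of an FMISO study is summarised
by its mean and SD (defaults 0.813 and 0.223) and is non-normal. A single
moment-matched lognormal cannot reproduce this faithfully *and* support the
HV definition: with mean 0.813 and SD 0.223 an i.i.d. right-skewed marginal
puts roughly 5 % of brain voxels above T/B 1.2, which would swamp the
region-restricted hypoxic volume (~10 cm^3^ of spurious "hypoxia" inside the
tumour region, against a genuine lesion of ~2.4 cm^3^). Real backgrounds
carry their variance in spatial structure, not in a per-voxel tail. The
generator therefore assigns composition-weighted tissue levels
(grey > white ≫ CSF, the FMISO uptake ordering), stretches the contrast
about the mean by a factor solved at run time so the brain-wide mean and SD
match the targets exactly in expectation — capping grey at T/B 1.10, safely
below threshold — and multiplies by mild lognormal voxel noise (CV 0.02)
that absorbs whatever variance the capped contrast cannot carry. The result
is non-normal with exact moments and a negligible spurious tail. The focal
hypoxic lesion is a contiguous blob at a fixed T/B level (default 1.52)
centred on the bulk-tumour surface — the dense-core/edge interface — and
sized to a fraction (default 0.13) of the bulk tumour volume, so HV lands at
~13 % of the T1Gd volume by construction.

**Virtual patient.** A single voxel seeded at 0.8 K in off-centre white
matter grows under ground-truth $(D, \rho)$ until the virtual T1Gd volume
reaches the diagnostic target (default 18.8 cm^3^, giving a T2 volume of
~47 cm^3^); the clock is aligned so that MRI is day 0. A second MRI follows
at day 13, treatment starts 5 days later with the standard plan built from
the day-13 masks, the ground-truth OER (default 2.5) applies inside the
synthetic HV, and the post-treatment MRI is taken 3 days after the final
fraction. The seed magnitude (0.8 K in one voxel) and the exact chunking of
the growth loop are generator conventions; observations are exact model
output under the stored parameters, which is what makes the recovery
properties sharp.

# Problem sizes and runtimes

The test suite and the acceptance script size their problems to run
comfortably on one CPU: the virtual-patient grid is 96^3^ voxels at 1 mm
(~3.3 × 10^5^ brain voxels), front-speed measurements use a 150-voxel 1D
bar fitted over days 300–1200 (late enough that the slowly decaying
front-speed transient of pulled waves is below the 5 % band), unit-level
pipeline tests use a 48^3^ patient with a 2 cm^3^ tumour, and oracle
comparisons (surface distances, dilation) run on ≤ 32^3^ grids where
brute force is exact and cheap. These sizes are the package's validation
choices, not model limits; the solver takes any grid the machine holds.

# What the tests do and do not show

Passing the suite shows the pieces are internally consistent and numerically
sound: conservation, boundedness, monotonicity in $\alpha$ and OER, the
OER/dose identity, agreement with closed forms and brute-force oracles, and
full-circle parameter recovery on data the model itself generated. It does
*not* show the model fits any real patient: the phantom has no gyri or
anisotropic tracts, the dose has no penumbra, hypoxia is binary and static,
chemotherapy is absorbed into $\alpha$, MRI segmentation error and
registration error do not exist here, and the detection thresholds 0.80/0.16
are assumed rather than measured. Claims about real-data performance require
real images, which this package deliberately does not ship.

# Known limitations

* Explicit time stepping; very large $D$ on fine grids forces small steps.
* No resection, no sublethal-damage repair, no re-oxygenation, no explicit
  chemotherapy model.
* The hypoxic focal lesion in the generator is a single contiguous blob at a
  constant T/B level; real hypoxia is patchy and graded.
* Surface distances are voxel-centre to voxel-centre, not sub-voxel mesh
  distances; Hausdorff-type metrics are not provided.
* `estimateDRho()` assumes the tumour is in its travelling-wave regime; very
  small or very recently seeded tumours violate that.
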