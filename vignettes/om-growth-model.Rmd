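---
title: "Modeling bursty outer-membrane growth and its fluorescence signature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling bursty outer-membrane growth and its fluorescence signature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omgrowth)
```

## The physical picture

Labeled outer-membrane (OM) proteins of growing Gram-negative cells form
diffraction-limited puncta that spread apart as the cell elongates, broaden,
occasionally split, and are retained at the poles, while in growth-arrested
cells they barely move. `omgrowth` models the OM as a two-dimensional,
incompressible, viscous fluid on a cylinder of fixed radius, with **no
diffusion**: the only motion is the laminar flow created by localized
insertion of new membrane material. Insertion is *bursty* — discrete events
that initiate at random positions and run for a random time — rather than
uniform, and the patchiness this produces is what makes labeled material
look punctate.

Three kinetic parameters control everything:

| parameter | meaning | unit | headline value |
|---|---|---|---|
| `kOn`  | event initiations per membrane area | µm⁻² s⁻¹ | 0.004 |
| `kIns` | area added per unit time by one active event | µm² s⁻¹ | 0.00064 |
| `tau`  | mean event duration (exponential) | s | ≈ 50 (derived) |

The product `tau * kIns` is the mean area inserted per event — the model's
patchiness scale. The cell radius (0.5 µm) and initial cylindrical length
(2 µm) are typical *E. coli* dimensions and are configurable; hemispherical
pole caps are deliberately outside the model (see *Limitations*).

## Mean-field growth law

Averaging the stochastic process gives a linear system for the cylindrical
area $A(t)$ and the number of active insertion sites $n(t)$:

$$\frac{dA}{dt} = k_\mathrm{ins}\, n, \qquad
  \frac{dn}{dt} = k_\mathrm{on}\, A - n/\tau .$$

Its dominant eigenvalue $\lambda$, the positive root of
$\lambda^2 + \lambda/\tau = k_\mathrm{on} k_\mathrm{ins}$, is the exponential
growth rate, so the doubling time is $t_2 = \ln 2/\lambda$. `solveTau()`
inverts this: given $(k_\mathrm{on}, k_\mathrm{ins})$ and $t_2$,

$$\tau = \frac{\lambda}{k_\mathrm{on} k_\mathrm{ins} - \lambda^2},
  \qquad \lambda = \ln 2 / t_2,$$

which exists iff $k_\mathrm{on} k_\mathrm{ins} > \lambda^2$ — slower
kinetics simply cannot sustain the requested growth rate, and the function
says so rather than returning a negative duration.
`meanfieldTrajectory()` evaluates the exact eigendecomposition solution (the
two eigenvalues are always real and distinct), not a discretization; the
test suite cross-checks it against an adaptive ODE solver. Along the
dominant eigenvector the site concentration is constant,
$n/A = \lambda/k_\mathrm{ins}$:

```{r}
p <- kineticParams(0.004, 0.00064, tDouble = 90 * 60)
tau(p)
steadySiteConcentration(p)   # sites per um^2
```

## The flow field

On the strip obtained by unwrapping the cylinder (axial coordinate $x$,
circumferential $y$ periodic with $P = 2\pi R$), each active event is a 2D
point source of area flux $Q = k_\mathrm{ins}$. Periodicity is enforced by
the method of images: source copies at $y + kP$. The package evaluates the
truncated sum (`velocityField()`, default 21 terms, $k = -10\ldots10$) and
also the exact infinite sum (`closedFormVelocity()`),

$$v_x = \frac{Q}{2P}\,
   \frac{\sinh(2\pi\Delta x/P)}{\cosh(2\pi\Delta x/P)-\cos(2\pi\Delta y/P)},
  \qquad
  v_y = \frac{Q}{2P}\,
   \frac{\sin(2\pi\Delta y/P)}{\cosh(2\pi\Delta x/P)-\cos(2\pi\Delta y/P)},$$

which serves as the independent oracle in the tests.

**Truncation error.** The axial tail of the image sum is one-sided (every
distant image pushes material outward), so truncating at $\pm K$ images
leaves a relative error that *grows* with axial distance: with $K = 10$ the
field is accurate to better than $10^{-3}$ within ~0.2 µm of a source (where
the direct term dominates), while far from all sources the error relative to
the local velocity scale is a few percent at $|\Delta x| \sim P$ and reaches
~30 % at $|\Delta x| = 5P$. The tests assert exactly this calibrated
profile, plus convergence as the truncation is widened. Two design
consequences:

* The inert pole boundaries are advected with the *circumferentially
  averaged* axial velocity, which for the infinite sum is exactly
  $\pm Q/(2P)$ per enclosed source. This keeps the pole boundaries vertical
  (they are rings of the cylinder, which the $y$-dependent truncated field
  would shear) and makes the area ledger exact: the domain area
  $P\,(x_R - x_L)$ equals the initial area plus every inserted increment to
  machine precision, at any truncation.
* Material points themselves move through the truncated field, so passive
  markers dilate apart at a rate very slightly below the area growth rate;
  the marker-divergence test quantifies this and still recovers
  $\ln 2/t_2$ within ensemble error.

A source is advected by all *other* sources' fields plus its own periodic
images; its own direct monopole is excluded (a monopole exerts no net force
on itself, and including the singular self-term would be meaningless
numerically). Patch vertices, by contrast, feel the full field including
their own source — that is precisely how inserted flux becomes patch area.

## The stochastic simulator

Each step of `runSimulation()` / `step()`:

1. **Terminate** events whose sampled lifetime has expired (drawn once at
   initiation from Exponential(τ) — equivalent in law to a memoryless
   per-step termination, but replayable and directly testable).
2. **Initiate** `rpois(1, kOn * A * dt)` events uniformly on the current
   cylindrical surface, each opening a regular polygon of area `kIns * dt`
   with the label (light/dark) of the current phase of the labeling
   schedule.
3. **Advect** every patch vertex and every source through the flow of the
   surviving active sources (explicit Euler by default, midpoint `"rk2"`
   available), and move the domain ends by the total inserted area over
   $2P$.

The step size follows `dt = min(tau/20, 1/(20 kOn A), 0.5 s)`: twenty steps
per mean event duration and per mean initiation interval keep the
exponential-duration and Poisson statistics finely sampled; the 0.5 s cap
keeps late, large-area stages accurate. At the headline kinetics the cap
binds throughout, and the per-event discretization bias in inserted area is
`kIns * dt/2` ≈ 0.5 % of the mean event area.

**Vertex count.** New polygons get
`clamp(round(6 + 4 log10(E[area]/1e-3)), 6, 24)` vertices, so larger patches
are smoother. A regular $n$-gon carries $\frac{n}{2\pi}\sin(2\pi/n)$ of its
circumcircle's area, so patch polygons systematically hold ~1–3 % less area
than the flux their source injected; the ledger tests use 48 vertices where
sub-percent accuracy is asserted. The singularity guard (no velocity
evaluation within $10^{-4}$ µm of a source image) only protects degenerate
configurations — a patch's own vertices are born at finite radius.

**Label bookkeeping.** Material inserted while an event is active gets the
label of the *current* schedule phase: at a light→dark boundary every
surviving event spawns a fresh dark patch at its source, and rendering
paints patches in birth order, so the dark core correctly occludes the light
material it displaced outward. This is also the punctum-splitting mechanism:
a dark region of roughly PSF width inserted inside a bright patch splits it
into two resolvable puncta, while a much narrower one only broadens it.
`labelAreas()` rasterizes this painter's model to measure how much light,
dark, and original material is actually present — unlike a naive sum of
polygon areas, which double-counts displaced material.

The simulation owns a single seeded RNG; states carry the RNG stream, so any
run replays bit-for-bit from its seed, and patch geometry provably never
feeds back on the area process (with the same seed, a run with and without
patch tracking produces the identical area trajectory — asserted in the
tests, and exploited to run large kinetics-only ensembles cheaply).

## The virtual microscope

`renderMicrograph()` reproduces a widefield epifluorescence image of the
light-labeled material:

1. rasterize the patches onto the strip at `superSample` (default 4×)
   sub-pixel resolution, painter's order;
2. wrap the strip onto the cylinder: a surface element at circumferential
   angle θ projects to lateral position $R\sin\theta$ with defocus
   $R\cos\theta$ relative to the focal plane through the cylinder axis —
   the Jacobian of this projection is what makes the cell outline bright at
   its top and bottom edges;
3. convolve each of `zLayers` (default 9) defocus slices with its PSF and
   sum;
4. integrate onto 68 nm camera pixels (6.8 µm physical pixels at 100×) and
   apply noise: Poisson photon noise on the signal, a constant background
   offset, and Gaussian read noise.

The PSF is the defocused-Gaussian approximation: lateral
$\sigma(z) = \sigma_0\sqrt{1+(z/z_R)^2}$ with
$\sigma_0 = 0.21\,\lambda/\mathrm{NA}$ (≈ 86 nm at 575 nm / NA 1.4) and
$z_R = 2\lambda n/\mathrm{NA}^2$ ($n = 1.515$), with the slice integral
damped by the Strehl-like factor $1/(1+(z/z_R)^2)$. Puncta metrics depend on
the lateral width, which this captures; a vectorial Born–Wolf model is a
declared extension stub. Noise defaults — `photonScale` 2×10⁴ counts per µm²
of labeled area, read noise 2 counts, offset 100 counts — were chosen once
so that a mean-sized insertion patch (≈ 0.032 µm²) images at a peak
signal-to-noise of ~20, comfortably detectable yet far from saturating;
absolute intensities are arbitrary and nothing in the analysis depends on
them (detection is scale-invariant by construction).

## Puncta analytics

`detectSpots()` finds local maxima above a robust background threshold and
refines them by 2D Gaussian fitting. The background level is the
half-sample mode of the frame (robust even when the cell covers much of the
field) and the noise scale comes from the *lower* tail of the intensity
distribution, which fluorescent signal cannot inflate; the threshold is
`bg + 5 sigma`. Maxima closer than the Rayleigh radius
$0.61\lambda/\mathrm{NA} \approx 250$ nm are merged — the mechanism that
makes punctum counts saturate at roughly perimeter/250 nm as labeling
accumulates, and hence makes appearance curves plateau.

`linkTracks()` is greedy nearest-neighbour linking (default 300 nm per
frame), with newborn tracks annotated as splits of the nearest existing
track within the split radius. `kymographTopEdge()` samples the image row at
the top cell edge; `punctaCurve()` averages per-frame counts over
replicates; `fitSigmoid()` fits the logistic
$N(t) = N_\mathrm{max}/(1+e^{-(t-t_0)/s})$ by Levenberg–Marquardt and
reports the initial appearance rate as the maximum slope
$N_\mathrm{max}/(4s)$. Degenerate curves are *flagged*, never silently
fitted: a curve that never rises within the sampled window (rate
ill-conditioned) or whose fitted plateau extrapolates beyond twice the
observed maximum (plateau not sampled) returns `converged = FALSE` with a
diagnostic. `pairwiseDivergence()` fits exponential separation rates of
neighbouring tracks — zero for growth-arrested cells, $\approx\lambda$ for
growing ones — and classifies pairs polar/cylindrical by axial position.

## The parameter screen

`runScan()` sweeps (kOn, kIns) pairs — default 10×10 log-spaced plus the
headline pair, 101 sets, 21 replicates each — with τ constrained by the
common doubling time, runs the full simulate→render→detect→fit pipeline
under continuous light insertion, and reports the appearance rate and
maximum count normalized by the initial outline perimeter
($2L_0 + 4R$; the normalization convention is recorded in the result
metadata). Per-pair failures are recorded and the scan continues.
`classifyConsistent()` then labels each pair by interval membership against
*user-supplied* experimental bounds; the package ships an editable,
explicitly synthetic bounds file
(`inst/extdata/experimental-bounds-synthetic.yaml`) rather than hard-coded
truth, because such bounds are read graphically from experiments. Across
mean insertion sizes the plateau count falls as `tau * kIns` grows — larger
patches make fewer distinguishable spots — which is the qualitative
mechanism the screen exploits.

## Problem sizes in the tests

The suite runs full pipelines at deliberately modest sizes, chosen as the
smallest ensembles whose assertions are statistically meaningful: 100
kinetics replicates for the doubling-time check (±9 min band, observed
ensemble sd ≈ 9 min), 50 replicates × 10 checkpoints for the mean-field
equivalence (3 standard errors), 12 marker-pair replicates for the
divergence rate, 3 replicates × 3 parameter sets for the screen checks. The
acceptance script runs 100 full-geometry 90-minute simulations.

## Limitations

* **No pole caps.** The cylinder ends are inert, advected boundaries;
  insertion is uniform over the whole current surface. Interval dilation is
  therefore position-independent, and true *polar retention* — material
  trapped in insertion-free hemispherical caps — is outside the model. The
  polar/cylindrical track classification is provided for data analysis, but
  simulated divergence rates do not differ near the ends.
* **No diffusion, no membrane mechanics.** Material moves only by insertion
  flow; bilayer viscoelasticity is taken as negligible on growth
  timescales. The growth-arrested (`kOn = 0`) limit is therefore perfectly
  static.
* **No division.** Septation, constriction and daughter-pole formation are
  not modeled; simulations should be read as single elongating cells over
  roughly one doubling.
* **Exponential durations, uniform initiation.** The event sampler is the
  single extension point for non-exponential durations or spatially biased
  initiation; the shipped model deliberately uses the simplest assumptions.
* **Simulated optics only.** The renderer aims at the features puncta
  metrics depend on (lateral PSF width, defocus blur, edge brightening,
  shot noise), not at photometric realism: absolute intensities, spectral
  effects and photobleaching are out of scope, and analysis of real image
  stacks is limited to generic calibrated TIFFs.
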