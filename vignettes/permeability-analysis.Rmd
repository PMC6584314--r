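---
title: "Quantifying barrier permeability in a radial organ-on-chip: models, estimators, and their validity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying barrier permeability in a radial organ-on-chip}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(permchip)
```

## The measurement

In a radial two-compartment microfluidic barrier chip, an endothelial
monolayer lines an annular apical (blood-side) channel that surrounds a
central cylindrical basolateral (tissue-side) chamber; the two are
separated by a pillar scaffold perforated with micron-scale pore slits.
A fluorescent tracer (FITC-dextran of defined molecular weight) is
perfused through the apical channel at fixed molarity (312.5 nM), and a
widefield time-lapse (one 16-bit frame per minute, about two hours)
records its passive leak into the central chamber.

The analysis reduces each frame to region-of-interest statistics, forms
the **normalized intensity**

$$ I(t) \;=\; \frac{B(t) - bg}{A_{eq} - bg}, $$

where $B(t)$ is the mean basolateral intensity, $A_{eq}$ the mean apical
intensity after the apical channel has reached its equilibrium value,
and $bg$ a background estimate, and converts the early-time slope of
$I(t)$ into an apparent permeability

$$ P_{total} \;=\; \frac{V}{S}\,\frac{dI}{dt}, $$

with $V/S$ the receiver volume-to-exchange-surface ratio. For a
cylindrical chamber with full-perimeter exchange, $V/S = r/2$ exactly
(0.045 cm for an 1800 µm chamber — height cancels). Barrier resistances
add in series, so the bare-scaffold contribution measured in an
acellular device is removed by

$$ \frac{1}{P_e} \;=\; \frac{1}{P_{total}} - \frac{1}{P_{scaffold}}, $$

leaving the endothelial permeability $P_e$.

Two deliberate geometry conventions deserve note. First, $V$ is the
*receiver* (central-chamber) volume: a receiver-normalized intensity
slope is dimensionally converted by the receiver's $V/S$, and pore-level
geometry is absorbed into $P_{scaffold}$, which is measured through the
same wall. Second, $S$ is the full cylindrical wall area even though the
pore slits open only a fraction of it (3 µm per 50 µm pitch, open
fraction 0.06); the same convention is used when simulating and when
analysing, so recovered values are directly comparable to the assumed
truths, and the open fraction is available on the geometry object for
anyone wanting the other convention.

## The forward model (what the simulator emulates)

`compartment_transport()` implements a two-compartment exchange model:

* the apical concentration rises exponentially to the inlet value,
  $C_a(t) = C_0(1 - e^{-t/\tau})$, with $\tau$ = 300 s by default. A
  finite fill time (dead volume, tubing) is what makes the protocol's
  exclusion of pre-equilibrium frames meaningful, and it exercises the
  gating logic; $\tau = 0$ gives a clamped donor.
* the receiver obeys $dC_b/dt = k\,(C_a - C_b)$ with
  $k = P_{total}/(V/S)$ and $C_b(0) = 0$.

The solution is evaluated in closed form (a two-exponential, with the
confluent limit handled when $k \to 1/\tau$), not numerically; the test
suite cross-checks it against an independent ODE solver at tight
tolerance. Key consequence: the receiver saturates with time constant
$1/k$, which for fast barriers is *minutes* (15 min for a bare scaffold
at $5\times10^{-5}$ cm/s), and that saturation is what limits the
raw-slope estimator below.

`render_frames()` draws each frame with the standard gain-scaled camera
model: expected signal `brightness_gain * C * exp(-bleach_rate t)` per
pixel under each ROI, shot noise as `photon_gain * Poisson(signal /
photon_gain)`, plus a constant detector offset (400 counts) and Gaussian
read noise (SD 10 counts), clipped to 16 bits. The variance of a uniform
region is therefore `photon_gain * (mean - background) + read_noise^2`,
which the suite verifies on ≥10⁴ pixels. Defaults (gain 0.5, apical
equilibrium near 30,000 counts) were chosen once so that slope CIs are
visibly nonzero at single-run level; they are testability choices, not
claims about any particular microscope. One seed drives everything;
per-frame substreams are derived deterministically from (seed, frame),
so identical configurations give bit-identical stacks.

An optional 2D mode (`sector_factors =`) replaces the well-mixed
receiver with explicit finite differences on a polar grid of the disk
(24 rings × 36 wedges by default), with a flux boundary at the wall
whose local permeability varies azimuthally. It exists to create the
azimuthal heterogeneity that the per-sector analysis is meant to detect.
Azimuthal diffusion is skipped inside the inner quarter radius, where
wedge cells are tiny and effectively uniform; this lifts an otherwise
crippling explicit-stability limit without visible effect on the wall
region that drives the sector signal.

What the generator does *not* emulate: advective flow inside
compartments, pore-resolved 3D transport, fluorophore photophysics
beyond exponential bleaching, stage drift, flat-field error, or cell
segmentation. Passing recovery tests therefore demonstrate correctness
of the *analysis chain under the stated transport model*, not robustness
to those real-world artifacts.

## The analysis chain and its tunables

| parameter | default | units | role |
|---|---|---|---|
| `rel_tol`, `window` | 2%, 5 frames | — | apical-equilibrium gate: first frame from which `window` consecutive apical means lie within `rel_tol` of the median of the final quartile |
| background | first-frame background-ROI median | counts | robust, tracer-free by construction; `background = 0` restores the literal un-subtracted ratio |
| weights | $1/sd^2$ | — | inverse-variance reading of "weighting with the standard deviations"; per-frame SDs are per-pixel sample SDs ($n-1$) |
| CI multiplier | 1.96 | — | normal approximation; with ≥30 frames the t-quantile difference is negligible |
| `pixel_size` | 10 | µm/px | rasterization of the chip layout into masks |
| `n_sectors` | 12 | — | equal-angle wedges of the receiver disk, counterclockwise from +x |

Window selection: the plateau is the vertex of a weighted quadratic fit
and the inflection the second-derivative root of a weighted cubic fit,
both over all post-equilibrium frames (fit the whole profile, then
restrict); the slope window is [equilibrium, inflection), else
[equilibrium, plateau), else all post-equilibrium frames, never fewer
than three frames (widened with a warning). A detected point outside the
observed window counts as absent, and if the cubic's root is outside but
the quadratic's vertex is inside, the vertex ends the window. Negative
fitted slopes are reported, not clamped; significance is judged by
whether the CI excludes zero.

The slope standard error is the residual-scaled weighted-normal-equations
value — identical to `lm(weights = 1/sd^2)`. This makes the CI invariant
to the overall scale of the SDs, which matters because the per-pixel ROI
SD used for weighting is not the sampling SD of the ROI *mean*.

## Two estimators, and where each is valid

`method = "slope"` is the assay-standard estimator:
$P = (V/S)\,\widehat{dI/dt}$ on the selected window. Under the forward
model $dI/dt = k(C_a/C_0 - I)$, so the raw slope equals $k$ only while
$I \ll 1$. Once the window extends toward saturation the estimate is
biased low by roughly the window-average of $e^{-kt}$. This is a
property of the estimator, not of the implementation: at study-condition
kinetics ($P_{total} = 1.15\times10^{-5}$ cm/s, equilibrium gate opening
near $t = 20$ min) the bias is tens of percent, and for a bare scaffold
($1/k = 15$ min) the receiver is ~74% equilibrated before the first
usable frame, so most of the signal is simply gone. The package
documents this honestly rather than hiding it: recovery tests for the
raw-slope estimator are run in its validity regime ($k\,t \ll 1$; e.g.
$P_{total} \le 10^{-6}$ cm/s for a two-hour acquisition at this
geometry), where the suite demonstrates median recovery within ±10%.

`method = "log-slope"` fits the *same weighted straight line* to
$-\log(1 - I)$, with SDs propagated as $sd/(1-I)$ and frames at $I \ge 1$
dropped. Under the two-compartment model this line has slope exactly
$k$ at any degree of saturation (post-equilibrium, the donor fill term
is an additive constant in the log), so it recovers fast-barrier truths
to well under a percent at default noise. It is the package's own
design addition; the default remains `"slope"` because that is the
protocol the assay prescribes.

The 95% CIs quantify *fit noise only*. With tens of thousands of ROI
pixels per frame the fit-noise CI is very tight (relative half-width
~0.1–0.3%), while two error sources it deliberately ignores are larger:
the shared normalization-denominator error ($A_{eq}$ and background are
estimated once and scale every point together) and, for `"slope"`, the
saturation bias. Empirical coverage of the truth is therefore poor at
fast kinetics, and the CIs should be read as precision of the line fit,
not total uncertainty. Triplicate devices, as in practice, are the
appropriate route to between-run error.

## The changepoint fixture

`two_slope_profile()` generates the synthetic profile used to validate
the inflection detector: 120 one-minute samples rising with a gentle
slope, steepening threefold at the 60 min breakpoint, flat after 90 min,
plus i.i.d. Gaussian noise (SD 0.01). The breakpoint is placed where the
*smaller* slope precedes the larger one. This is deliberate: an
inflection is a sign change of curvature, so a profile whose slope only
ever decreases (steep → gentle → flat) is concave everywhere and has no
inflection for a curvature-based detector to find — the cubic's
second-derivative root then falls far outside the observation window and
the detector correctly reports absence (the suite asserts exactly this).
The accelerating shape is also the physically realistic one: fill-limited
start, transport-limited rise, then plateau. On this fixture the global
weighted cubic recovers the breakpoint with a small systematic late bias
(median ≈ 63 min over 20 seeds, all within ±5 min of 60), the price of
summarizing a piecewise profile with a single cubic.

## Numerical choices and degenerate inputs

* Polynomial detectors declare degeneracy when the leading coefficient is
  below $10^{-12}$ of the data's natural scale (`sd(y)` over the window
  span to the appropriate power) and return absence rather than a wild
  root.
* Zero per-frame SDs (possible on constant synthetic frames) are replaced
  by the smallest positive SD in the window before weighting.
* The confluent transport case $k = 1/\tau$ uses the exact
  $1 - e^{-kt}(1+kt)$ limit, switched at relative distance $10^{-12}$.
* Scaffold subtraction refuses $P_{total} \ge P_{scaffold}$ ("barrier
  faster than scaffold"); in pipeline batch mode the run is reported with
  $P_e$ unresolved instead of aborting the batch.
* Rasterization uses pixel-centre sampling; masks are pairwise disjoint
  by construction and the barrier annulus belongs to no ROI.

## Problem sizes in the test and acceptance suites

The suites were sized to be thorough yet quick as a deliberate package
choice: recovery experiments use 10 seeds per fixture at 120 frames and
10 µm/px (the defaults of the packaged fixture configs); module-level
simulations use coarser rasters (20 µm/px) and 30–60 frames; the sector
heterogeneity check runs 5 seeds of the 2D mode at
$P_{total} = 1.15\times10^{-6}$ cm/s, inside the slope estimator's
linear regime (at fast fixture kinetics the *normal* sectors saturate
within the window while the starved sector keeps rising, which genuinely
inverts late-window slope ordering — a transport effect worth knowing
about when interpreting sector maps of leaky devices).

## Known limitations

* The raw-slope estimator's saturation bias at fast kinetics, described
  above; use `"log-slope"` (or shorter windows at earlier times) when
  $1/k$ is comparable to the usable acquisition span.
* CIs understate total uncertainty (normalization-denominator error and
  estimator bias are not propagated).
* The sector analysis converts each wedge with the global $V/S$; wedge
  cross-talk by in-chamber diffusion blurs azimuthal contrast, so sector
  permeabilities are comparative, not absolute.
* The shear utilities use the infinite-parallel-plate closure
  $\tau = 6\mu Q/(w h^2)$ with viscosity an explicit input (default
  1.0 mPa·s). For the 200 × 100 µm channel this gives 2.5 dyn/cm² at
  5 µL/min; published figures near 2.73 dyn/cm² for the same nominal
  conditions imply a slightly higher viscosity (≈1.09 mPa·s) or an
  aspect-ratio correction, so ramp schedules are generated in *shear*
  space and flow is derived, keeping the schedule exact under whatever
  viscosity the user supplies. Literal flow-ramp figures of
  100 µL/min-scale starts are inconsistent with sub-0.1 dyn/cm²
  starting shears at this geometry (they would imply ~50 dyn/cm²) and
  are treated as a units slip; the package ramps from the stated shear
  endpoints.
* No drift or flat-field correction, no arbitrary chip topologies beyond
  the radial two-ring layout, no z-resolved geometry.
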