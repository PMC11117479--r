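---
title: "gradchip: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{gradchip: models, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gradchip)
```

gradchip is a digital twin of a two-layer PDMS microfluidic chip that
establishes combinatorial drug concentration gradients in arrays of
serially connected culture chambers. This vignette explains the models the
package implements, the parameters that matter, the numerical choices, and
where the design was genuinely open.

## The chamber cascade and the replacement-fraction model

Each chamber array is a column of m culture chambers threaded by
independently valved feed channels. A *pulse* — flow at speed u for
duration t — exchanges part of each chamber's liquid with the stream. The
package's core abstraction is the per-chamber *replacement fraction*
f_i ∈ (0,1): after one pulse,

$$ c_i' = (1 - f_i)\,c_i + f_i\,c_\mathrm{inlet}. $$

Because the stream is progressively diluted as it loads each chamber, the
fractions are non-increasing downstream; the calibrated profile of the
reference device for a 4 s pulse at 5 mm/s is

```{r}
default_profile()$fractions
```

Repeated identical pulses unroll to the closed form
$c_i = c_\mathrm{inlet}(1-(1-f_i)^n)$ (`steady_state_limit()`), which the
test suite checks against the literal fold of `apply_pulse()` to machine
precision. Two idealizations are deliberate:

* **Single-pulse gradients.** The device's reported chamber concentrations
  equal inlet × f_i, i.e. one pulse into drug-free chambers. The package
  treats this as the canonical "gradient established" state; multi-pulse
  dynamics are exposed separately through `run_schedule()`.
* **Exact species independence.** The three channels of an array exchange
  through disjoint 250 × 790 µm windows of a 250 × 2000 µm chamber and
  interact negligibly; the model makes that exact — pulsing one species
  never moves another.
* **Path mirror symmetry.** The chip layout is symmetric, so a bottom-up
  pulse (Path-2) applies the fraction list in reverse chamber order.
  Path-2 fractions are never printed for the reference device; the mirror
  is a stated modeling convention, which the finite-volume solver
  reproduces to discretization accuracy.

## The finite-volume transport solver

`fv_replacement_fractions()` recomputes the cascade from first principles
instead of trusting the calibration. The domain is the flow path of a
single feed channel, reduced to a depth-averaged 2D strip: straight
channel segments alternate with chambers; inside a chamber the channel
crosses the exchange window, and the remaining chamber volume is a
stagnant side cavity whose depth is chosen to conserve the chamber volume
(area / window length − channel width). Velocity is plug flow at the inlet
speed confined to the channel strip — divergence-free by construction —
and zero in the cavity; the cavity couples to the moving stream by
transverse diffusion.

Numerics: explicit first-order upwind advection plus central
(conservative, two-point flux) diffusion on a rectangular grid, no-flux
walls, Dirichlet unit concentration at the inlet face, upwind outflow. The
time step obeys the joint advective/diffusive stability limit with a 0.5
safety factor; a user-supplied step that violates the limit is refused
with a diagnostic rather than silently clipped. Because fluxes are
face-based, tracer mass in a sealed domain is conserved to floating-point
rounding (tested at 1e-6 relative per step), and the open-domain budget
(mass gained = inflow − outflow) holds to the same accuracy.

Parameters and defaults:

| parameter | default | why |
|---|---|---|
| diffusivity | 1.0e-10 m²/s | typical for growth-factor-scale proteins in water; not published for the reference simulation |
| channel width | 100 µm | typical valve-compatible rounded flow channel; not printed on the device drawings |
| channel segment length | 500 µm | chamber-to-chamber spacing is unpublished; configurable |
| grid | 24 cells per exchange window | resolves the window with ~33 µm cells; runs a 4 s pulse in ~1 s |
| inlet speed / duration | 5 mm/s / 4 s | the device's calibration conditions (3, 5 and 10 mm/s are the device's stated options) |

With these defaults — chosen once, before any output was compared — the
solver gives a chamber-1 replacement fraction of about 0.17 against the
calibrated 0.2248, inside the ±35% band that the acceptance criterion
allows for the unpublished mesh/diffusivity/geometry, and a strictly
decreasing cascade. The downstream decay is shallower than the calibrated
profile (the depth-averaged cavity underestimates how much tracer each
chamber strips from the stream), which is why the solver is a *property*
check — monotonicity, conservation, limits, mirror symmetry, the chamber-1
band — and not a bit-exact reproduction. The calibrated
`default_profile()` remains the quantitative reference for dose planning.

One contract nuance: user-facing `replacement_profile()` objects require
fractions strictly inside (0,1), but the solver's limiting cases (duration
→ 0 gives exact zeros downstream; duration → ∞ gives full replacement)
legitimately touch the boundary, so the solver constructs its profile with
an internal flag admitting 0 and 1. The limits are part of the test suite.

## The valve multiplexer

Each flow channel is addressed by a unique k-subset of n control valves;
pressurizing a valve closes every channel whose address contains it
(pressurized = closed, standard push-down membrane polarity — the
polarity is a convention the hardware description leaves implicit). A
channel flows iff none of its k address valves is pressurized, so opening
exactly one channel means pressurizing the complement of its address. Any
two distinct k-subsets differ in at least one valve, hence every assigned
design passes exhaustive isolation verification; `verify_isolation()`
still performs the full patterns × channels check and reports violating
pairs for malformed designs. Addresses are assigned in lexicographic
k-subset order purely for reproducibility; the physical chip's routing is
unknown and only the counts (7 valves, 24 channels, k = 3) are
constrained.

## Dose planning and the reporting raster

Chamber concentrations are reported to the nearest multiple of 1% of the
inlet concentration, half away from zero (`report_rounded()`): a 500
ng/mL inlet reports on a 5 ng/mL raster, 200 ng/mL on 2 ng/mL, 1000 ng/mL
on 10 ng/mL. This rule was reverse-engineered as the unique simple
convention consistent with all fifteen printed gradient values of the
reference device; it is documented as a *reporting* convention, not a
physical claim, and raw concentrations are always carried alongside. No
printed value sits on a rounding tie under the defaults. Dose ranks
(1 = highest) follow the chamber index under Path-1 and its mirror under
Path-2; a chamber's combination code joins the per-drug ranks in channel
order, e.g. `1+5+5` for high + low + low.

## Synthetic cell cohorts

`synth_cells()` seeds each chamber with independent cells that
differentiate (lose the stemness reporter) with probability

$$ p(d) = b + \frac{m - b}{1 + e^{-s\,(d - d_0)}} $$

where d is the chamber's summed drug concentration. Defaults: baseline
b = 0.05 (spontaneous differentiation near control), plateau m = 0.5
(the observed overdose readout of roughly half the cells differentiating),
midpoint d₀ = 150 ng/mL and slope s = 0.1 per ng/mL, so the transition
sits inside a PDGF-scale gradient (113–225 ng/mL) and both plateaus are
identifiable from five doses. These were fixed a priori and are not tuned
to any test outcome.

What the generator emulates: binomially noisy per-chamber reporter counts
with a monotone dose dependence and seed-reproducibility. What it does
not: the biphasic (beneficial-low / adverse-high) behavior of real growth
factors, drug–drug interaction, cell division and migration between
chambers, or image segmentation — cohorts are already boolean reporter
calls, because the upstream image-processing step of the real pipeline is
not described. A green recovery test therefore establishes that the
analysis stack (fraction, per-repeat summary, ML fit) is correct on data
from a known generator, not that the logistic model fits real cells.

`fit_response_model()` maximizes the binomial likelihood over all four
parameters under a box-free reparameterization (logit for the plateaus,
log for midpoint and slope) with BFGS; with 2000 cells per chamber across
five doses it recovers b and m within ±0.05. Condition summaries use the
sample (n−1) standard deviation across repeats — the dispersion formula is
not stated by the reference — and flag summaries built from fewer than
five repeats, the device's stated minimum.

## Degenerate inputs and tie-breaks

* Counts < 1, non-positive concentrations, inconsistent profile/chamber
  lengths, unknown channels/species: validation errors naming the field.
* `stemness_fraction()` on an empty cohort is an error, not 0.
* Rounding ties go half away from zero; none occur for the reference
  inlets.
* The middle chamber of an odd cascade has the same rank under both paths.

## Known limitations

* The solver is first-order (upwind) and depth-averaged: no parabolic
  velocity profile, Taylor dispersion, valve-membrane mechanics, or 3D
  effects; agreement with the calibrated fractions is at the
  tens-of-percent level by design.
* Cross-channel leakage is exactly zero in the model; the real device only
  shows "no observable" premature mixing.
* The experiment planner assigns conditions to arrays injectively in
  listed order; it does not optimize factorial coverage.
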