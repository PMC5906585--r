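---
title: "A coarse-grained 3D agent-based model of vocal fold injury and repair"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A coarse-grained 3D agent-based model of vocal fold injury and repair}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vfheal)
```

## The model

`vfheal` simulates the acute inflammatory and repair response of vocal fold
mucosa after injury as a hybrid agent-based model.  The tissue is a regular
lattice of cubic *patches* (15 um side by default).  Each patch carries

* eight diffusing, decaying signalling chemicals (TNF-alpha, TGF-beta1, FGF,
  MMP8, IL-1beta, IL-6, IL-8, IL-10), in arbitrary concentration units;
* three structural ECM proteins (collagen, elastin, hyaluronan), each split
  into an *intact* and a *fragment* layer; and
* a damage level in [0, 1].

Mobile cell agents -- platelets, neutrophils, macrophages and fibroblasts --
live on the lattice, read the chemical state of their patch, and act once
per 30-minute *tick*: they migrate chemotactically, secrete chemicals,
fragment or deposit ECM, proliferate and die.  Wounding sets damage inside a
configured axis-aligned ellipsoid, seeds degranulating platelets there, and
deposits an initial bolus of TGF-beta1, IL-1beta and MMP8.  Cells are
recruited from the tissue surrounding the wound at Poisson rates
proportional to local chemoattractant totals.

The model's scientific core is the treatment of the two very different time
scales: cells act on a 30-minute tick while chemical diffusion is stable
only at second-scale steps.

## Coarse-grained diffusion

Each chemical obeys the diffusion-decay equation
$\partial c/\partial t = D \nabla^2 c - \gamma c$.  The explicit 6-neighbour
finite-difference step on the lattice is a convolution with a $3^3$ stencil
with centre weight $1 - 6\lambda - \gamma\Delta t$ and face-neighbour
weights $\lambda = D\Delta t / \Delta x^2$.  Keeping all weights
non-negative requires
$$\Delta t \le \frac{\Delta x^2}{6D + \gamma \Delta x^2},$$
which for the fastest diffuser ($D = 900\,\mu m^2/min$, $\Delta x = 15\,\mu m$,
$\gamma = 0$) is 2.5 s.  (We fold decay into the bound: with $\gamma > 0$
the classical $\Delta x^2/6D$ step would leave the centre weight slightly
negative.  With the zero-decay defaults the bound is the classical one.)

A single micro step $\Delta t$ is shared by all chemicals, set by the
fastest diffuser, so one $m = \lceil \mathrm{tick}/\Delta t_{max} \rceil$
applies to every field; at the 30-minute tick and the tissue diffusivities,
$m = 720$.  Because $m$ explicit steps are $m$ convolutions with the
stencil $f$, one tick is a single convolution with the $m$-fold
self-convolution $f_m$:
$$c(\cdot, \tau + \Delta\tau) = c(\cdot, \tau) * f_m .$$

`compose_kernel()` builds $f_m$ by binary exponentiation in the spectral
domain: the stencil is embedded in an enclosing FFT box, transformed once,
raised elementwise to the $m$-th power and transformed back.  This is
repeated convolution-squaring executed in Fourier space.  When the full
support $2m+1$ fits the box the result is exact to round-off (this covers
every oracle test); for $m = 720$ the box wraps tail mass that lies beyond
roughly six standard deviations of the diffusion profile
($\sigma \approx 15.5$ patches per axis), a relative error around $10^{-8}$
-- far below the truncation loss discussed next.

### Kernel truncation

The untruncated $f_{720}$ spans $1441^3 \approx 3\times10^9$ patches, but
its mass is concentrated in a small central window.  `truncate_kernel()`
keeps a centred window *without renormalising*: the lost mass is real,
measured, and reported (`retained_mass_fraction`); a run warns if the loss
exceeds the configured tolerance.  The presets use a fixed 147-wide window.
A direct Monte-Carlo check (`kernel_truncation_loss_mc()`, simulating the
equivalent 720-step lattice walk via per-walker multinomial direction
counts) puts the mass outside that window at $\sim 10^{-5}$ -- the window
is, if anything, generous.  Configurations may instead request a minimum
mass coverage (default 0.993) and let the package pick the narrowest
adequate width.

### Boundaries

No boundary condition is physically privileged here; we use zero-padded
linear convolution (absorbing: chemical leaving the tissue block is lost),
implemented with real FFTs and padding just past the kernel half-width.
Within one tick the composed kernel lets mass wander beyond the block and
return -- the oracle (`diffuse_naive()`) therefore steps on a domain padded
by $m$ before cropping, which reproduces the convolution exactly.  A
periodic mode exists solely for conservation tests: a uniform field is a
fixed point for $\gamma = 0$, and scales by $(1-\gamma\Delta t)^m$ per tick
otherwise; both are verified to $10^{-10}$.

## Agent rules and their calibration

The biology fixes who does what; almost no rates are quantified.  All
quantitative behaviour lives in `rule_table()` and is config-overridable;
the shipped defaults are order-of-magnitude choices calibrated once so that
the canonical healing time course emerges at the workstation (`desk`)
scale:

* **Platelets** exist only on wounded patches, are sessile, and secrete
  TGF-beta1, IL-1beta and MMP8 for a 24-tick (12 h) degranulation window.
* **Neutrophils** are recruited at a Poisson rate tracking the
  platelet-derived IL-1beta pulse, so the influx starts within hours and
  collapses with degranulation; stochastic turnover with a 2-day mean
  lifetime then drains the population.  Activated neutrophils secrete
  TNF-alpha and MMP8.
* **Macrophages** follow the neutrophil-derived TNF-alpha wave (6-day mean
  lifetime), secrete the broad cytokine panel including IL-10, and clear
  fragment debris on their patch.  IL-10 damps TNF-alpha/IL-1beta secretion
  multiplicatively ($1/(1 + c_{IL10}/K)$), the model's resolution switch.
* **Fibroblasts** activate under TGF-beta1/FGF, proliferate under
  growth-factor stimulus with a per-patch contact-inhibition cap, and
  deposit ECM.  Net collagen synthesis is suppressed by local TNF-alpha and
  MMP8 (TNF-alpha inhibits type-I collagen synthesis; MMP8 is a
  collagenase), so collagen accumulates only as inflammation resolves --
  around day 3 at the shipped defaults -- while hyaluronan, nearly immune
  to fragmentation, accumulates from day 1.
* **ECM fragmentation** converts a per-protein fraction of intact mass to
  fragments wherever TNF-alpha *or* MMP8 exceeds its threshold; fragments
  emit danger signals and intact ECM repairs damage.

Chemotaxis is a one-patch-per-tick biased walk over the six face
neighbours: with probability `p_follow` the agent takes the
strictly-best-scoring neighbour (weighted sum of attractant
concentrations), staying put on ties; otherwise it steps uniformly.
Activation is sticky.  Agent order within a tick is an explicit seeded
shuffle.

None of these defaults is a measured biological constant, and we make no
claim of quantitative fidelity; the calibration targets are the
*qualitative* landmarks below.

## Tick orchestration

Each tick runs seed-cells, cell-function, ECM-function, ECM-fragmentation,
chemical diffusion and world-update, in that order, with two buffering
rules: every phase reads the chemical fields *published at tick start*, and
everything secreted goes to a separate buffer that diffusion consumes after
the last secreting phase (the secretion barrier).  Only the update phase
publishes.  Consequently the "overlapped" plan -- diffusion computed
alongside the remaining coarse-grain work -- is bit-identical to sequential
execution; the test suite asserts `identical()` over 48-tick desk runs at
three seeds.  This overlap-transparency is the testable content of running
field work and agent work on separate resources.

Updating agents against the *pre*-diffusion chemical state is a
convention, chosen for determinism and buffering clarity; a post-diffusion
variant (fields diffused first, agents read the fresh state, secretions
diffuse one tick later) is available via
`phase_plan(chemical_state = "post-diffusion")`.  The two differ only in
within-tick bookkeeping, not in the physics over a run.

## Scales, presets and what the tests show

* `human_full` -- 1390 x 1006 x 110 patches (20.85 x 15.09 x 1.65 mm),
  1.72 M neutrophils, 0.97 M macrophages, 12.20 M fibroblasts.  Shipped for
  configuration arithmetic and documentation; never executed by tests.
* `desk` -- 139 x 101 x 11 patches, cell counts scaled by the volume ratio
  (1727 / 974 / 12249).  Patch width and tick are unchanged, so the entire
  kernel calculation ($\Delta t$, $m = 720$ at zero decay, widths) is
  identical to full scale; a 336-tick (7-day) run takes a few minutes on
  one CPU.
* `micro` -- 25^3 patches for oracle-scale tests and smoke runs.

The desk world is a thin slab, and with absorbing boundaries a large share
of each chemical's mass exits vertically every tick; absolute
concentrations are therefore much lower than a full-scale run would give,
which is why the pattern predicates use landmark times and relative levels
only (they are invariant to uniform rescaling of a series).  Passing the
pattern suite at desk scale shows the *dynamic structure* of the model --
the ordering and timing of cellular waves and ECM responses -- not
quantitative agreement with tissue measurements, and not behaviour at the
full physiological scale.

The verification suite (`default_patterns()`, shipped as
`extdata/healing-patterns.yaml`) encodes the canonical wound-healing
record: neutrophils arrive within hours and peak by day 1-2 before
declining; macrophages peak between days 2 and 4; fibroblasts start
proliferating on day 1; collagen accumulates from day 3; hyaluronan is
first seen around day 3.  At the shipped defaults, 7-day desk runs at
seeds 1-3 pass all of these except hyaluronan onset: the model accumulates
hyaluronan from day 1 (activated fibroblasts secrete it immediately, and
fragmentation barely touches it), a known model-data discrepancy that the
suite marks `expected_fail` and asserts *as a failure* rather than hiding.
Patterns whose windows extend to day 14 ship with the suite but are only
evaluated on long runs.

## Numerical choices

* FFTs are real-to-complex via the FFTW3 library (C shim in `src/`);
  padded sizes are rounded up to products of 2, 3 and 5.
* Kernels are cropped per axis to `2n - 1` before planning -- wider offsets
  can only touch absorbed mass -- which keeps the thin-slab desk grid cheap.
* Negative convolution round-off (at the $10^{-16}$ level) is clamped to
  zero so concentration fields stay non-negative.
* The spectral power uses elementwise binary exponentiation in double
  precision.
* Onset detection: first tick exceeding the day-0 level by 10% (or 10% of
  the series maximum when the day-0 level is zero); day `d` spans ticks
  `[48(d-1), 48d)` at the 30-minute tick.
* Degenerate inputs: zero-severity wounds are no-ops; `D = 0` with
  `gamma = 0` yields an unconstrained (infinite) stability bound and
  `m = 1`; empty worlds tick cleanly.

## Reproducibility

A world carries its own RNG state, seeded from the configuration; every
stochastic decision (placement, shuffles, movement, recruitment,
proliferation, death) draws from it in a fixed order.  Two runs from the
same configuration are bit-identical, independent of the caller's RNG and
of the phase plan.

## Known limitations

* Rates, thresholds and lifespans are calibrated defaults, not fitted
  parameters; quantitative calibration against tissue cytokine data is out
  of scope.
* The wound is an axis-aligned ellipsoid in a box world; no vasculature,
  mechanics, or non-box geometry.
* One shared micro step for all chemicals slightly over-resolves the slow
  diffusers (their per-step $\lambda$ is below the stability limit); this
  costs nothing at tick granularity since all chemicals share one $m$.
* Macrophage debris clearing acts on ECM fragment mass; there is no
  separate dead-cell field.
* The 14-day patterns (fibroblast decline, full sigmoid plateau) are
  shipped but unverified at the default 7-day run length.
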