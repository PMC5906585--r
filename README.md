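# vfheal

A 3D hybrid agent-based simulator of acute vocal fold (mucosal) injury and
repair, for researchers studying wound-healing dynamics and for
methods work on multi-scale tissue simulation.

Vocal fold injury triggers a stereotyped cascade: platelet degranulation,
a neutrophil influx peaking around day 1, a macrophage wave peaking days
2–4, fibroblast proliferation from day 1, and extracellular-matrix
rebuilding with collagen accumulating from day 3.  `vfheal` simulates this
cascade on a lattice of 15-µm tissue patches carrying eight diffusing
signalling chemicals (TNF-α, TGF-β1, FGF, MMP8, IL-1β, IL-6, IL-8, IL-10)
and three ECM proteins (collagen, elastin, hyaluronan), with mobile
platelet, neutrophil, macrophage and fibroblast agents acting once per
30-minute tick.

## The core method: coarse-grained diffusion

Chemical transport follows ∂c/∂t = D ∇²c − γc.  The explicit 6-neighbour
lattice step is a convolution with a 3×3×3 stencil (centre
1 − 6λ − γΔt, neighbours λ = DΔt/Δx²), stable only for
Δt ≤ Δx²/6D — 2.5 s for the fastest chemical (D = 900 µm²/min, Δx = 15 µm).
Rather than stepping 720 times per 30-minute tick, the m micro-steps are
collapsed into a single convolution with the m-fold self-composed stencil:

    c(·, τ + Δτ) = c(·, τ) ∗ f_m,   m = ⌈Δτ / Δt_max⌉ = 720.

The untruncated f₇₂₀ spans 1441³ ≈ 3·10⁹ patches; `vfheal` composes it
spectrally (binary exponentiation of the stencil's FFT) and truncates it to
a dense central window — 147-wide in the shipped presets — tracking the
real, unrenormalised mass loss (~10⁻⁵ per tick, verified by Monte-Carlo
random walks).  Fields are convolved with real FFTs (FFTW) under absorbing
boundaries.  A naive m-step stencil oracle ships alongside and the FFT path
matches it to 10⁻¹⁰ relative error in the test suite.

Agent behaviour (chemotaxis as a biased face-neighbour walk, secretion,
activation, recruitment, proliferation, ECM fragmentation and repair) is
fully configuration-driven via `rule_table()`; the shipped defaults are
calibrated so the canonical healing time course emerges at the reduced
`desk` scale.  Runs are bit-reproducible from `(configuration, seed)`, and
the overlapped execution plan is bit-identical to the sequential one.

## Worked example

A 7-day wound-healing course at the workstation (`desk`) preset — the full
physiological geometry reduced ~10× per axis with identical patch width,
tick and kernel mathematics:

```r
library(vfheal)

cfg <- make_preset("desk")          # 139 x 101 x 11 patches, seed 1
kernels <- prepare_kernels(build_kernels(cfg), cfg$grid)
world <- init_world(cfg)            # wounded, platelets degranulating
r <- run(world, 336, kernels = kernels)   # 336 ticks = 7 days

ts <- r$timeseries
ts[ts$tick %in% c(0, 24, 48, 96, 144, 240, 336),
   c("tick", "n_neutrophil", "n_macrophage", "n_fibroblast",
     "ecm_collagen_intact", "ecm_hyaluronan_intact", "damage_total")]
```

```
 tick n_neutrophil n_macrophage n_fibroblast ecm_collagen_intact ecm_hyaluronan_intact damage_total
    0         1727          974        12249               0.000                     0         3367
   24         3435          987        14300               8.421                  6158         3319
   48         2743         1112        14338             148.339                 18249         3074
   96         1649         1176        14200             576.633                 42504         2648
  144          991         1183        14040            1326.637                 66479         2429
  240          354         1027        13766            5004.624                113626         2127
  336          134          813        13497           14442.911               159797         1885
```

The neutrophil count doubles within half a day and peaks at tick ~25
(day 0.5) before draining; macrophages peak around day 2.4; fibroblasts
exceed 110% of their resident count during day 1; collagen stays near zero
while inflammation is high and accumulates steeply after day ~3, while
hyaluronan rises from day 1; total damage falls as ECM is rebuilt.

Checking those dynamics against the qualitative wound-healing record:

```r
report <- run_pattern_suite(ts, default_patterns())
report[, c("name", "status", "observed")]
```

```
                              name        status observed
    neutrophils-arrive-first-hours          pass 4.17e-02
     neutrophil-peak-by-day-1-or-2          pass 5.21e-01
  neutrophil-decline-by-day-3-or-4          pass 1.78e-01
          macrophage-peak-days-2-4          pass 2.44e+00
            fibroblast-onset-day-1          pass 3.54e-01
    fibroblast-decline-day-7-to-14 not-evaluated       NA
  collagen-accumulation-from-day-3          pass 3.12e+00
            collagen-sigmoid-shape not-evaluated       NA
 collagen-above-uninjured-baseline          pass 1.33e+03
            hyaluronan-onset-day-3 expected-fail 9.17e-01
hyaluronan-peak-with-inflammatory-peak not-evaluated     NA
```

`observed` is the measured landmark (peak or onset day, or a relative
level).  `hyaluronan-onset-day-3` is a *known* model–data discrepancy —
the model accumulates hyaluronan from day ~0.9 instead of day 3 — shipped
as `expected_fail` and asserted as such.  Day-14 patterns are evaluated
only on runs long enough to cover them.

A command-line front end is installed with the package
(`exec/vfheal`): `vfheal kernel` prints micro-step/kernel arithmetic,
`vfheal run` executes a configuration and writes CSV/VTK output, and
`vfheal check-patterns` evaluates a time series against a pattern file.

## Package layout

- `R/` — world model, diffusion engine, agent engine, orchestrator,
  output sampling, pattern verification, presets.
- `src/fft3.c` — real 3D FFT primitives (FFTW3).
- `inst/extdata/` — YAML presets (`human_full`, `desk`, `micro`) and the
  healing-pattern suite.
- `vignettes/model-and-methods.Rmd` — the model, its assumptions,
  calibration and limitations.
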