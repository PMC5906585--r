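# Workstation-scale configuration: the full-scale world reduced ~10x per
# axis.  Patch width (15 um) and tick (30 min) are unchanged so the entire
# kernel calculation (micro step, steps per tick, kernel widths) is
# identical to the full-scale model; only the world extent, cell counts
# (scaled by the volume ratio 154,429 / 153,817,400) and wound size shrink.
name: desk
grid: {nx: 139, ny: 101, nz: 11, patch_width: 15}
seed: 1
tick_minutes: 30
chemicals:
  - {name: TNFa,  diffusivity: 900, decay: 0.020}
  - {name: TGFb1, diffusivity: 780, decay: 0.004}
  - {name: FGF,   diffusivity: 780, decay: 0.004}
  - {name: MMP8,  diffusivity: 780, decay: 0.010}
  - {name: IL1b,  diffusivity: 900, decay: 0.020}
  - {name: IL6,   diffusivity: 810, decay: 0.015}
  - {name: IL8,   diffusivity: 900, decay: 0.015}
  - {name: IL10,  diffusivity: 900, decay: 0.008}
agents: {neutrophil: 1727, macrophage: 974, fibroblast: 12249}
wound: {center: [69, 50, 5], radii: [17, 12, 4], severity: 1.0}
kernel: {max_width: 147}
baseline_ecm: 0
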