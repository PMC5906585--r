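# Full physiological-scale human vocal-fold configuration.
# Documentation / arithmetic preset: 153,817,400 patches covering
# 20.85 x 15.09 x 1.65 mm at 15 um patch width, ~14.9 million cells.
# Not intended to be executed on a workstation; use the desk preset.
name: human_full
grid: {nx: 1390, ny: 1006, nz: 110, patch_width: 15}
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
agents: {neutrophil: 1720000, macrophage: 970000, fibroblast: 12200000}
wound: {center: [695, 503, 55], radii: [170, 120, 40], severity: 1.0}
kernel: {max_width: 147}
baseline_ecm: 0
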