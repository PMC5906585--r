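# Miniature 25^3 world for oracle-scale tests and quick smoke runs.
# Cell counts scaled by the volume ratio 15,625 / 153,817,400.
name: micro
grid: {nx: 25, ny: 25, nz: 25, patch_width: 15}
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
agents: {neutrophil: 175, macrophage: 99, fibroblast: 1239}
wound: {center: [12, 12, 12], radii: [6, 6, 4], severity: 1.0}
kernel: {max_width: 147}
baseline_ecm: 0
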