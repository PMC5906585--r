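# Qualitative wound-healing patterns evaluated against a run's time series.
# Windows are in elapsed days ("day 1" of healing covers elapsed days 0-1).
# Patterns whose window exceeds the run length are reported not-evaluated.
patterns:
  - name: neutrophils-arrive-first-hours
    column: n_neutrophil
    kind: onset-by
    window: [0.0, 0.25]
  - name: neutrophil-peak-by-day-1-or-2
    column: n_neutrophil
    kind: peak-in-window
    window: [0.0, 2.0]
  - name: neutrophil-decline-by-day-3-or-4
    column: n_neutrophil
    kind: decline-after
    window: [0.0, 4.0]
    params: {probe_day: 4.0, fraction: 0.6}
  - name: macrophage-peak-days-2-4
    column: n_macrophage
    kind: peak-in-window
    window: [1.0, 4.0]
  - name: fibroblast-onset-day-1
    column: n_fibroblast
    kind: onset-by
    window: [0.0, 1.0]
  - name: fibroblast-decline-day-7-to-14
    column: n_fibroblast
    kind: decline-after
    window: [0.0, 14.0]
    params: {probe_day: 14.0, fraction: 0.7}
  - name: collagen-accumulation-from-day-3
    column: ecm_collagen_intact
    kind: onset-by
    window: [2.0, 7.0]
  - name: collagen-sigmoid-shape
    column: ecm_collagen_intact
    kind: sigmoid-shape
    window: [0.0, 14.0]
  - name: collagen-above-uninjured-baseline
    column: ecm_collagen_intact
    kind: relative-to-baseline
    window: [3.0, 7.0]
    params: {baseline: 0.0, side: above}
  - name: hyaluronan-onset-day-3
    column: ecm_hyaluronan_intact
    kind: onset-by
    window: [2.0, 4.0]
    expected_fail: true   # the model accumulates hyaluronan from day 1
  - name: hyaluronan-peak-with-inflammatory-peak
    column: ecm_hyaluronan_intact
    kind: co-timing
    window: [0.0, 14.0]
    params: {other: n_macrophage, tol_days: 2.0}
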