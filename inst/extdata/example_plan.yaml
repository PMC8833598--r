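# Resection-cavity-like scenario on the packaged synthetic phantom:
# three cross-firing conformal microbeam fields, normalized so the PTV
# D98% on the EQD2 scale matches the clinical reference.
phantom:
  shape: [32, 32, 8]
  spacing: [2, 2, 2]
  body: {type: cylinder, radius: 30, density: 1}
  target: {label: ptv_gbm_cavity, center: [40, 26, 8], diameter: 15}
  oars:
    - {label: brain_stem, center: [33, 32, 8], diameter: 10}
    - {label: cochlea, center: [44, 38, 8], diameter: 5}
beams:
  angles: [0, 120, 240]
  entrance_peak_dose: 100
  valley_fraction: 0.05
  effective_mu: 0.17
  dilation_px: 1
evaluation:
  reference_d98: 53.05
  constraints:
    - {structure: brain_stem, metric: Dmax, threshold: 54}
    - {structure: cochlea, metric: Dmax, threshold: 45}
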