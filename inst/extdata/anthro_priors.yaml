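# Anthropometric and axis-alignment priors used by the lower-body estimator.
# Angles in degrees, lengths in meters.
axis_segment:
  - {segment: femur, side: right, mu_deg: 84.0, sigma_deg: 2.4}
  - {segment: tibia, side: right, mu_deg: 92.0, sigma_deg: 1.2}
  - {segment: femur, side: left,  mu_deg: 96.0, sigma_deg: 2.4}
  - {segment: tibia, side: left,  mu_deg: 88.0, sigma_deg: 1.2}
lengths:
  - {name: tibia, mu: 0.411, sigma: 0.026, lmin: 0.344, lmax: 0.479}
  - {name: femur, mu: 0.394, sigma: 0.030, lmin: 0.326, lmax: 0.480}
  - {name: femoral_head_separation, mu: 0.187, sigma: 0.009, lmin: 0.0, lmax: 0.409}
discrepancy:
  - {name: femur, sigma: 0.008}
  - {name: tibia, sigma: 0.006}
window_sharpness: 100.0
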