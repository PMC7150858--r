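wtp_mean:
  long_tablet: 0.5
  capsule: 1.0
  medium: -2.5
  large: -5.0
  yellow: 0.7
  blue: -0.6
  red: -1.1
wtp_sd:
  long_tablet: 0.1
  capsule: 0.3
  medium: 0.7
  large: 2.0
  yellow: 0.1
  blue: 0.1
  red: 0.4
scale_mu: 0.0
scale_sigma: 0.5
seed: 1.0
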