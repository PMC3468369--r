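{
  "archetypes": ["stubby", "thin", "mushroom", "filopodium"],
  "weights": [0.250050069596497, 0.400080111354395, 0.250050069596497, 0.0998197494526104],
  "length_meanlog": [-0.356674943938732, 0.336472236621213, 0.182321556793955, 1.6094379124341],
  "length_sdlog": [0.330088107334032, 0.330088107334032, 0.330088107334032, 0.27507342277836],
  "neck_meanlog": [-0.747214401830221, -0.967584026261706, -0.980829253011726, -1.09861228866811],
  "neck_sdlog": [0.0403142308997736, 0.0403142308997736, 0.0403142308997736, 0.0403142308997736],
  "ratio_meanlog": [-0.0512932943875506, 0, 0.470003629245736, -0.105360515657826],
  "ratio_sdlog": [0.22, 0.22, 0.25, 0.22],
  "area_coupling": 0.7,
  "area_noise_sdlog": 0.25,
  "calibration": {
    "targets": {
      "length": 7.97,
      "head_width": 2.02
    },
    "achieved": {
      "length": 7.96933366014885,
      "head_width": 2.01998595124424
    },
    "knobs": {
      "filopodium_weight": 0.0998197494526104,
      "length_sdlog_scale": 1.10029369111344,
      "neck_sdlog": 0.0403142308997736
    }
  }
}
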