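{
  "spot_um": 85,
  "thicknesses_um": [340, 510, 680],
  "voids_um": [680, 850, 1020, 1360, 1700, 2040],
  "hu_air": -1000,
  "hu_material": 120,
  "hu_classes": [
    {"name": "core", "lower": 0,    "upper": null, "lower_open": true,  "upper_open": true},
    {"name": "gg1",  "lower": -300, "upper": 0,    "lower_open": true,  "upper_open": false},
    {"name": "gg2",  "lower": -500, "upper": -300, "lower_open": true,  "upper_open": false},
    {"name": "gg3",  "lower": -750, "upper": -500, "lower_open": false, "upper_open": false}
  ],
  "visibility_rules": [
    {"t_um": 340, "g_min_visible_um": 1700, "kernel_scope": "hard"},
    {"t_um": 510, "g_min_visible_um": 1360, "kernel_scope": "hard"},
    {"t_um": 680, "g_min_visible_um": 1020, "kernel_scope": "both"}
  ],
  "band_anchors": [
    {"band": "gg3", "lower_hu": -750, "upper_hu": -500, "t_um": 340, "g_um": 1020},
    {"band": "gg2", "lower_hu": -500, "upper_hu": -300, "t_um": 510, "g_um": 850},
    {"band": "gg1", "lower_hu": -300, "upper_hu": 0,    "t_um": 680, "g_um": 680}
  ],
  "visibility_threshold": 0.2,
  "psf_sigma_mm": 0.6,
  "resin_price_per_ml": 0.16
}
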