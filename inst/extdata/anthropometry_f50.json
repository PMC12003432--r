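{
  "version": "1.0",
  "description": "Embedded 50th-percentile adult-female anthropometric constants used to build the fixture models. Segment masses and radii of gyration follow standard adult-female segment inertia tables (fractions of body mass and segment length); torso stadium dimensions follow 50th-percentile female chest breadth/depth and trunk length. These are documented assumptions, swappable by pointing the builder at another file.",
  "units": { "length": "m", "mass": "kg", "density": "g/mL", "force": "N" },
  "body_mass": 64.0,
  "segments": {
    "humerus": { "length": 0.310, "mass": 1.63, "com_frac": 0.575, "rg_trans_frac": 0.278, "rg_long_frac": 0.148 },
    "forearm": { "length": 0.250, "mass": 0.88, "com_frac": 0.456, "rg_trans_frac": 0.261, "rg_long_frac": 0.094 },
    "hand":    { "length": 0.170, "mass": 0.36, "com_frac": 0.440, "rg_trans_frac": 0.240, "rg_long_frac": 0.160 }
  },
  "gh_center": [-0.010, -0.030, 0.170],
  "hand_point": [0.0, -0.080, 0.0],
  "torso": {
    "rect_half_width": 0.019,
    "end_radius": 0.119,
    "height": 0.520,
    "base_density": 1.00,
    "center": [-0.0926, -0.166, 0.0],
    "native_breast_density": 0.95,
    "region_volume": 405,
    "region_center": [0.0, -0.10, 0.09],
    "region_radius": 0.045
  },
  "dynamometer": {
    "rotation_contact_forearm": 0.265,
    "planar_contact_from_gh": 0.333
  },
  "implant": { "volume_cc": 405, "projection_cm": 4.4 },
  "fmax_female_scale": 0.6
}
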