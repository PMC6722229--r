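{
  "_comment": "Documentation-only default cutoff configuration for the structural auto-QC profile. The z-score cutoffs were calibrated on a specific reference population (bad vs. good+questionable) and are population-specific: recalibrate with `qc calibrate` before relying on them. Bounds are on the z scale; a missing bound means one-sided.",
  "schema_version": 1,
  "profile": "t1",
  "bad_threshold": 3,
  "cutoffs": [
    {"metric": "snr",  "lower_z": -2.55, "upper_z": null, "directionality": "lower_is_worse"},
    {"metric": "svnr", "lower_z": -1.65, "upper_z": null, "directionality": "higher_is_worse"},
    {"metric": "cnr",  "lower_z": -0.95, "upper_z": null, "directionality": "lower_is_worse"},
    {"metric": "cvnr", "lower_z": -0.40, "upper_z": null, "directionality": "higher_is_worse"},
    {"metric": "tctv", "lower_z": -1.10, "upper_z": null, "directionality": "lower_is_worse"},
    {"metric": "fwhm", "lower_z": null, "upper_z": 1.30, "directionality": "higher_is_worse"},
    {"metric": "com",  "lower_z": null, "upper_z": 2.85, "directionality": "higher_is_worse"}
  ]
}
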