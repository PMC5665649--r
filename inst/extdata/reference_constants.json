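{
  "comment": "Equilibrium dissociation constants for iGluR amino-terminal domain dimerization. 'labeled' marks the fluorophore carrier; bound entries carry the direction of the one-sided limit. Units: molar.",
  "constants": [
    {"family": "kainate", "unlabeled": "GluK1", "labeled": "GluK1", "kd_M": 1.2e-06, "ci_lower_M": 8e-07, "ci_upper_M": 1.7e-06, "bound": null, "label_type": "DyLight488"},
    {"family": "kainate", "unlabeled": "GluK2", "labeled": "GluK1", "kd_M": 1.8e-06, "ci_lower_M": 1.5e-06, "ci_upper_M": 2.2e-06, "bound": null, "label_type": "DyLight488"},
    {"family": "kainate", "unlabeled": "GluK2", "labeled": "GluK2", "kd_M": 1.63e-07, "ci_lower_M": 1.13e-07, "ci_upper_M": 2.35e-07, "bound": null, "label_type": "DyLight488"},
    {"family": "kainate", "unlabeled": "GluK2", "labeled": "GluK5", "kd_M": 9.4e-09, "ci_lower_M": 8e-09, "ci_upper_M": 1.1e-08, "bound": null, "label_type": "DyLight488"},
    {"family": "kainate", "unlabeled": "GluK3", "labeled": "GluK3", "kd_M": 5e-11, "ci_lower_M": null, "ci_upper_M": null, "bound": "upper", "label_type": "DyLight488"},
    {"family": "kainate", "unlabeled": "GluK4", "labeled": "GluK1", "kd_M": 1.46e-07, "ci_lower_M": 1.16e-07, "ci_upper_M": 1.84e-07, "bound": null, "label_type": "DyLight488"},
    {"family": "kainate", "unlabeled": "GluK4", "labeled": "GluK2", "kd_M": 5.7e-08, "ci_lower_M": 4.6e-08, "ci_upper_M": 7.1e-08, "bound": null, "label_type": "DyLight488"},
    {"family": "kainate", "unlabeled": "GluK4", "labeled": "GluK4", "kd_M": 1e-03, "ci_lower_M": null, "ci_upper_M": null, "bound": "lower", "label_type": "absorbance"},
    {"family": "kainate", "unlabeled": "GluK5", "labeled": "GluK1", "kd_M": 1.8e-08, "ci_lower_M": 1.5e-08, "ci_upper_M": 2.2e-08, "bound": null, "label_type": "DyLight488"},
    {"family": "kainate", "unlabeled": "GluK5", "labeled": "GluK2", "kd_M": 1.2e-08, "ci_lower_M": 1.0e-08, "ci_upper_M": 1.4e-08, "bound": null, "label_type": "DyLight488"},
    {"family": "kainate", "unlabeled": "GluK5", "labeled": "GluK5", "kd_M": 3.5e-04, "ci_lower_M": null, "ci_upper_M": null, "bound": null, "label_type": "absorbance"},
    {"family": "ampa", "unlabeled": "GluA1", "labeled": "GluA1", "kd_M": 2.84e-08, "ci_lower_M": 1.4e-08, "ci_upper_M": 5.8e-08, "bound": null, "label_type": "EGFP"},
    {"family": "ampa", "unlabeled": "GluA2", "labeled": "GluA1", "kd_M": 2.9e-09, "ci_lower_M": 1.6e-09, "ci_upper_M": 5.6e-09, "bound": null, "label_type": "EGFP"},
    {"family": "ampa", "unlabeled": "GluA2", "labeled": "GluA2", "kd_M": 2.11e-08, "ci_lower_M": 1.7e-08, "ci_upper_M": 2.7e-08, "bound": null, "label_type": "DyLight488"},
    {"family": "ampa", "unlabeled": "GluA2", "labeled": "GluA4", "kd_M": 3.26e-08, "ci_lower_M": 1.9e-08, "ci_upper_M": 5.9e-08, "bound": null, "label_type": "EGFP"},
    {"family": "ampa", "unlabeled": "GluA3", "labeled": "GluA1", "kd_M": 8.3e-09, "ci_lower_M": 6e-09, "ci_upper_M": 1.2e-08, "bound": null, "label_type": "EGFP"},
    {"family": "ampa", "unlabeled": "GluA3", "labeled": "GluA2", "kd_M": 1.3e-09, "ci_lower_M": 1.0e-09, "ci_upper_M": 1.7e-09, "bound": null, "label_type": "DyLight488"},
    {"family": "ampa", "unlabeled": "GluA3", "labeled": "GluA3", "kd_M": 5.2e-06, "ci_lower_M": 1.7e-06, "ci_upper_M": 1.4e-05, "bound": null, "label_type": "unlabeled"},
    {"family": "ampa", "unlabeled": "GluA3", "labeled": "GluA4", "kd_M": 9.1e-08, "ci_lower_M": 6e-08, "ci_upper_M": 1.37e-07, "bound": null, "label_type": "EGFP"},
    {"family": "ampa", "unlabeled": "GluA4", "labeled": "GluA1", "kd_M": 6.2e-08, "ci_lower_M": 1.5e-08, "ci_upper_M": 2.18e-07, "bound": null, "label_type": "EGFP"},
    {"family": "ampa", "unlabeled": "GluA4", "labeled": "GluA4", "kd_M": 3.18e-07, "ci_lower_M": 1.45e-07, "ci_upper_M": 7.3e-07, "bound": null, "label_type": "EGFP"}
  ]
}
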