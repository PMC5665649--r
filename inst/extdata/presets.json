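{
  "comment": "Synthetic FDS-SV experiment presets: tracer-titration and dilution designs for kainate and AMPA receptor amino-terminal domain dimerization, parameterized by the measured dissociation constants as ground truth. X is the fluorophore carrier. koff_s null means instantaneous equilibrium kinetics.",
  "presets": {
    "GluK1_self_titration": {"design": "titration", "self": true, "tracer_M": 1e-09, "series_min_M": 3e-10, "series_max_M": 4e-05, "n_series": 12, "kd_x_M": 1.2e-06, "s1_x": 3.8, "s2_x": 5.8, "ffr": 1.5, "koff_s": null},
    "GluK2_self_titration": {"design": "titration", "self": true, "tracer_M": 1e-09, "series_min_M": 2e-09, "series_max_M": 4.99e-07, "n_series": 12, "kd_x_M": 1.63e-07, "s1_x": 3.8, "s2_x": 5.8, "ffr": 1.5, "koff_s": null},
    "GluK3_self_dilution": {"design": "dilution", "self": true, "series_min_M": 5e-11, "series_max_M": 1.2e-06, "n_series": 12, "kd_x_M": 5e-11, "kd_bound": "upper", "s1_x": 3.8, "s2_x": 5.8, "ffr": 1.5, "koff_s": null},
    "GluK4_self_dilution": {"design": "dilution", "self": true, "series_min_M": 3e-07, "series_max_M": 2.9e-05, "n_series": 8, "kd_x_M": 1e-03, "kd_bound": "lower", "s1_x": 3.8, "s2_x": 5.8, "ffr": 1.5, "koff_s": null, "channel": "absorbance"},
    "GluK1_x_GluK2_titration": {"design": "titration", "self": false, "tracer_M": 1e-09, "series_min_M": 3e-10, "series_max_M": 2e-05, "n_series": 12, "kd_x_M": 1.2e-06, "kd_y_M": 1.63e-07, "kd_xy_M": 1.8e-06, "s1_x": 3.8, "s2_x": 5.8, "s1_y": 3.8, "s2_y": 5.8, "s_xy": 5.6, "ffr": 1.5, "koff_s": null},
    "GluK1_x_GluK4_titration": {"design": "titration", "self": false, "tracer_M": 2e-10, "series_min_M": 2e-10, "series_max_M": 1.2e-06, "n_series": 12, "kd_x_M": 1.2e-06, "kd_y_M": 1e-03, "kd_xy_M": 1.46e-07, "s1_x": 3.8, "s2_x": 5.8, "s1_y": 3.8, "s2_y": 5.8, "s_xy": 5.6, "ffr": 1.5, "koff_s": null},
    "GluK1_x_GluK5_titration": {"design": "titration", "self": false, "tracer_M": 2e-10, "series_min_M": 2e-10, "series_max_M": 5e-06, "n_series": 12, "kd_x_M": 1.2e-06, "kd_y_M": 3.5e-04, "kd_xy_M": 1.8e-08, "s1_x": 3.8, "s2_x": 5.8, "s1_y": 3.8, "s2_y": 5.8, "s_xy": 5.6, "ffr": 1.5, "koff_s": null},
    "GluK2_x_GluK4_titration": {"design": "titration", "self": false, "tracer_M": 2e-10, "series_min_M": 2e-10, "series_max_M": 1.2e-06, "n_series": 12, "kd_x_M": 1.63e-07, "kd_y_M": 1e-03, "kd_xy_M": 5.7e-08, "s1_x": 3.8, "s2_x": 5.8, "s1_y": 3.8, "s2_y": 5.8, "s_xy": 5.6, "ffr": 1.5, "koff_s": null},
    "GluK2_x_GluK5_titration": {"design": "titration", "self": false, "tracer_M": 1e-09, "series_min_M": 2e-10, "series_max_M": 1.2e-06, "n_series": 12, "kd_x_M": 3.5e-04, "kd_y_M": 1.63e-07, "kd_xy_M": 9.4e-09, "s1_x": 3.8, "s2_x": 5.8, "s1_y": 3.8, "s2_y": 5.8, "s_xy": 5.6, "ffr": 1.5, "koff_s": null},
    "GluA1_self_dilution": {"design": "dilution", "self": true, "series_min_M": 1e-10, "series_max_M": 1.2e-06, "n_series": 12, "kd_x_M": 2.84e-08, "s1_x": 4.4, "s2_x": 6.25, "ffr": 1.5, "koff_s": 3e-04, "contaminant_s": 2.5, "contaminant_fraction": 0.05},
    "GluA4_self_dilution": {"design": "dilution", "self": true, "series_min_M": 5e-10, "series_max_M": 1.2e-06, "n_series": 12, "kd_x_M": 3.18e-07, "s1_x": 4.4, "s2_x": 6.25, "ffr": 1.5, "koff_s": 5e-03},
    "GluA1_x_GluA2_titration": {"design": "titration", "self": false, "tracer_M": 5e-10, "series_min_M": 2e-10, "series_max_M": 1.2e-06, "n_series": 12, "kd_x_M": 2.84e-08, "kd_y_M": 2.11e-08, "kd_xy_M": 2.9e-09, "s1_x": 4.4, "s2_x": 6.25, "s1_y": 3.8, "s2_y": 5.8, "s_xy": 5.6, "ffr": 1.5, "koff_s": null},
    "GluA1_x_GluA3_titration": {"design": "titration", "self": false, "tracer_M": 5e-10, "series_min_M": 2e-10, "series_max_M": 3e-06, "n_series": 12, "kd_x_M": 2.84e-08, "kd_y_M": 5.2e-06, "kd_xy_M": 8.3e-09, "s1_x": 4.4, "s2_x": 6.25, "s1_y": 3.8, "s2_y": 5.8, "s_xy": 5.6, "ffr": 1.5, "koff_s": null},
    "GluA1_x_GluA4_titration": {"design": "titration", "self": false, "tracer_M": 5e-10, "series_min_M": 2e-10, "series_max_M": 3e-06, "n_series": 12, "kd_x_M": 2.84e-08, "kd_y_M": 3.18e-07, "kd_xy_M": 6.2e-08, "s1_x": 4.4, "s2_x": 6.25, "s1_y": 3.8, "s2_y": 5.8, "s_xy": 5.6, "ffr": 1.5, "koff_s": null},
    "GluA2_x_GluA3_titration": {"design": "titration", "self": false, "tracer_M": 1e-09, "series_min_M": 2e-10, "series_max_M": 1.2e-06, "n_series": 12, "kd_x_M": 2.11e-08, "kd_y_M": 5.2e-06, "kd_xy_M": 1.3e-09, "s1_x": 3.8, "s2_x": 5.8, "s1_y": 3.8, "s2_y": 5.8, "s_xy": 5.6, "ffr": 1.5, "koff_s": null},
    "GluA4_x_GluA3_titration": {"design": "titration", "self": false, "tracer_M": 5e-10, "series_min_M": 2e-10, "series_max_M": 3e-06, "n_series": 12, "kd_x_M": 3.18e-07, "kd_y_M": 5.2e-06, "kd_xy_M": 9.1e-08, "s1_x": 4.4, "s2_x": 6.25, "s1_y": 3.8, "s2_y": 5.8, "s_xy": 5.6, "ffr": 1.5, "koff_s": null},
    "GluA4_x_GluA2_titration": {"design": "titration", "self": false, "tracer_M": 5e-10, "series_min_M": 1e-09, "series_max_M": 3e-06, "n_series": 12, "kd_x_M": 3.18e-07, "kd_y_M": 2.11e-08, "kd_xy_M": 3.26e-08, "s1_x": 4.4, "s2_x": 6.25, "s1_y": 3.8, "s2_y": 5.8, "s_xy": 5.6, "ffr": 1.5, "koff_s": null}
  }
}
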