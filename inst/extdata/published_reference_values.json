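{
  "glucosidase": {
    "corrected_total_ss": 0.001340,
    "corrected_total_tol": 5e-7,
    "pure_error_ss": 0.000003,
    "pure_error_tol": 5e-7,
    "pure_error_df": 2,
    "r_squared": 0.98,
    "f_regression": 60.8477,
    "f_lack_of_fit": 3.8582,
    "optimum": {"x1": 0.27, "x2": 0.0, "x3": 0.73, "predicted": 0.041}
  },
  "amylase": {
    "corrected_total_ss": 0.02544,
    "corrected_total_tol": 5e-6,
    "pure_error_ss": 0.00007,
    "pure_error_tol": 5e-6,
    "pure_error_df": 2,
    "r_squared": 0.99,
    "f_regression": 114.64,
    "f_lack_of_fit": 1.12,
    "optimum": {"x1": 0.56, "x2": 0.44, "x3": 0.0, "predicted": 0.021}
  }
}
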