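{
  "description": "Published cross-validated lasso models linking visual properties of office photographs to IRCS scores. Coefficients are on the standardized-predictor scale; intercepts are the predicted score at the standardized-feature origin. RMSEs are those reported for the 50-photo training and 10-photo test split.",
  "models": [
    {
      "outcome": "overall",
      "intercept": 2.910,
      "coefficients": [
        {"feature": "sqrt_greenery", "value": 0.010},
        {"feature": "geom_fractal_brightness_large", "value": 0.035},
        {"feature": "stat_fractal_brightness_large", "value": 0.033},
        {"feature": "color_fractal", "value": -0.121}
      ],
      "rmse_train": 0.231,
      "rmse_test": 0.256
    },
    {
      "outcome": "being_away",
      "intercept": 2.972,
      "coefficients": [
        {"feature": "sqrt_greenery", "value": 0.114},
        {"feature": "geom_fractal_brightness_large", "value": 0.005},
        {"feature": "color_fractal", "value": -0.106}
      ],
      "rmse_train": 0.247,
      "rmse_test": 0.241
    },
    {
      "outcome": "fascination",
      "intercept": 2.822,
      "coefficients": [
        {"feature": "sqrt_greenery", "value": 0.099},
        {"feature": "geom_fractal_brightness_large", "value": 0.005},
        {"feature": "stat_fractal_brightness_large", "value": 0.062},
        {"feature": "color_fractal", "value": -0.101}
      ],
      "rmse_train": 0.216,
      "rmse_test": 0.245
    },
    {
      "outcome": "extent",
      "intercept": 2.928,
      "coefficients": [],
      "rmse_train": 0.437,
      "rmse_test": 0.420
    }
  ]
}
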