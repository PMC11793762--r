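{"label":"synthetic ground-truth outcome model","intercept":24.72,"terms":[{"covariates":["gestational_age"],"exponents":[1],"coef":-0.06},{"covariates":["sbp_max"],"exponents":[1],"coef":0.02},{"covariates":["spo2"],"exponents":[1],"coef":-0.3},{"covariates":["platelets"],"exponents":[1],"coef":-0.009},{"covariates":["creatinine"],"exponents":[1],"coef":0.015},{"covariates":["ast"],"exponents":[1],"coef":0.008},{"covariates":["chest_pain"],"exponents":[1],"coef":0.7}]}
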