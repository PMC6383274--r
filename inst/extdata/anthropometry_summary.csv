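variable,control_n,control_mean,control_sd,case_n,case_mean,case_sd,published_t,published_p
age_years,342,61.69,10.73,342,62.42,10.72,0.894,0.372
bmi,342,23.46,3.18,342,25.52,3.50,8.032,<0.001
whr,342,0.90,0.06,342,0.92,0.06,4.392,<0.001
height_cm,342,163.30,8.10,342,162.81,7.94,0.799,0.424
weight_kg,342,62.62,10.04,342,67.75,11.35,6.262,<0.001
waist_cm,342,83.73,9.96,342,88.69,9.09,6.806,<0.001
hip_cm,342,92.79,9.26,342,96.07,8.22,4.898,<0.001
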