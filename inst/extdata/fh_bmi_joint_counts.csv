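cell,family_history,bmi_abnormal,cases,controls,published_or,published_ci_low,published_ci_high
neither,0,0,20,75,1.000,,
a_only,1,0,117,88,4.986,2.832,8.777
b_only,0,1,32,36,3.333,1.679,6.617
both,1,1,246,70,12.993,7.426,22.734
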