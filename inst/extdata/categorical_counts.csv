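variable,level,control,case,published_chisq,published_p
sex,male,175,172,0.119,0.730
sex,female,167,170,0.119,0.730
family_history,no,131,32,80.048,<0.001
family_history,yes,211,310,80.048,<0.001
bmi_category,low,12,5,63.165,<0.001
bmi_category,normal,194,103,63.165,<0.001
bmi_category,overweight,112,166,63.165,<0.001
bmi_category,obese,24,68,63.165,<0.001
whr,normal,74,53,4.492,0.034
whr,abnormal,268,289,4.492,0.034
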