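table,cell,value
infarct,fdg_mean,26.93
infarct,fdg_se,0.83
infarct,rbc_mean,33.89
infarct,rbc_se,1.56
infarct,ttc_mean,26.02
infarct,ttc_se,1.45
control,ratio_mean,35.12
control,ratio_se,1.91
diabetic,ratio_mean,18.82
diabetic,ratio_se,2.03
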