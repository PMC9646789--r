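agent,dose,dose_unit,fa
brequinar,3.78,nM,0.1
brequinar,10.28,nM,0.3
brequinar,19.54,nM,0.5
brequinar,36.82,nM,0.7
brequinar,101.74,nM,0.9
allium_sativum,72.42,ug/ml,0.1
allium_sativum,205.82,ug/ml,0.3
allium_sativum,403.56,ug/ml,0.5
allium_sativum,791.9,ug/ml,0.7
allium_sativum,2314.24,ug/ml,0.9
silymarin,65.58,ug/ml,0.1
silymarin,155.38,ug/ml,0.3
silymarin,267.26,ug/ml,0.5
silymarin,459.28,ug/ml,0.7
silymarin,1086.42,ug/ml,0.9
silibinin,27.12,nM,0.1
silibinin,105.84,nM,0.3
silibinin,243.76,nM,0.5
silibinin,567.62,nM,0.7
silibinin,2189.06,nM,0.9
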