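agent,Dm,m,r,dose_unit,is_combination
allium_sativum,202.972,1.26701,0.99998,ug/ml,FALSE
silymarin,133.538,1.5651,1,ug/ml,FALSE
silibinin,122.127,1.00184,0.99999,nM,FALSE
brequinar,9.76713,1.33376,0.99999,nM,FALSE
allium_sativum + brequinar,141.25,1.107,0.99889,ug/ml,TRUE
silymarin + brequinar,135.453,1.027,0.99999,ug/ml,TRUE
silibinin + brequinar,127.135,2.2,0.98999,nM,TRUE
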