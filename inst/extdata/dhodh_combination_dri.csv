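combination,fa_percent,ci_printed,dose_a,dose_b,dri_a,dri_b,label_printed
allium_sativum + brequinar,11,1.84,39.32,2.05,1.09,1.09,antagonism
allium_sativum + brequinar,39,1.46,142.08,6.96,1.38,1.35,antagonism
allium_sativum + brequinar,72,0.95,431.44,19.99,2.14,2.05,synergism
allium_sativum + brequinar,78,1.46,545.62,24.99,1.38,1.36,antagonism
allium_sativum + brequinar,98,0.47,5062.94,207.41,4.38,4.08,synergism
silibinin + brequinar,6,3.49,7.23,1.17,0.53,0.62,antagonism
silibinin + brequinar,44,1.14,97.72,8.26,1.85,1.61,antagonism
silibinin + brequinar,61,1.34,191.74,13.71,1.57,1.4,antagonism
silibinin + brequinar,78,1.4,426.52,24.99,1.5,1.36,antagonism
silibinin + brequinar,99,0.16,21481.5,474.52,19.63,9.33,synergism
silymarin + brequinar,17,1.33,47.76,2.92,1.46,1.55,antagonism
silymarin + brequinar,33,1.79,85.75,5.81,1.1,1.13,antagonism
silymarin + brequinar,72,1.03,245.88,19.99,1.84,2.05,additive
silymarin + brequinar,83,1.14,373.37,32.64,1.63,1.77,antagonism
silymarin + brequinar,98,0.55,1805.11,207.41,3.32,4.08,synergism
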