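index,oral,igivi,unit
mcr_i,7.4,12,ml/min/kg per nmol/l
isr_mean,656.7,465.6,pmol/min
insulin_clearance,2.16,2.53,l/min
di,4260,5000,ml/min/kg per nmol/l x pmol/min
insulin_auc_incremental,81706.1,38538.9,pmol/l x min
glp1_mean,37.4,12.5,ng/l
lactate_decay_beta,0.0009,0.0014,1/min
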