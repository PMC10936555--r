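clade,suborder,n_model,mean_model_rate_x100,n_cv,cv,age_my
Bembidion,Adephaga,40,0.096,213,0.046,48.6
Calathus,Adephaga,16,0.375,19,0.107,28.4
Chrysolina,Polyphaga,26,4.215,59,0.305,7.24
Cicindelidae,Adephaga,27,0.147,105,0.222,150.8
Dendroctonus,Polyphaga,13,0.837,20,0.386,46.2
Diabrotica,Polyphaga,12,0.050,36,0.018,37.2
Harpalus,Adephaga,14,0.082,29,0.054,65.5
Ips,Polyphaga,26,0.507,35,0.180,40.0
Pterostichus,Adephaga,15,0.259,49,0.096,37.2
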