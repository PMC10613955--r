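group_id,nucleus,atom_indices,delta_exp_ppm
H24,1H,31,5.12
H2a,1H,32,2.96
H2b,1H,33,2.27
H23a,1H,34,2.05
H23b,1H,35,2.05
Me1,1H,36;37;38,1.68
Me2,1H,39;40;41,1.62
Me3,1H,42;43;44,1.14
Me4,1H,45;46;47,1.14
Me5,1H,48;49;50,1.05
Me6,1H,51;52;53,0.98
Me7,1H,54;55;56,0.94
Me8,1H,57;58;59,0.86
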