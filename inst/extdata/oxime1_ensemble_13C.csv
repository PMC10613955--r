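functional,basis_set,r_squared,mae_ppm,rmse_ppm,max_abs_dev_ppm
B3LYP,DGDZVP,0.9993,0.75,0.95,2.09
B3PW91,DGDZVP,0.9993,0.71,0.93,2.21
CAM-B3LYP,DGDZVP,0.9994,0.62,0.84,2.15
HSEH1PBE,"6-31++G(d,p)",0.9991,0.89,1.09,3.17
mPW1PW91,"6-31+G(d,p)",0.9990,0.89,1.14,2.73
wB97XD,"6-31G(d,p)",0.9994,0.72,0.90,2.08
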