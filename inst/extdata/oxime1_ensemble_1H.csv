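functional,basis_set,r_squared,mae_ppm,rmse_ppm,max_abs_dev_ppm
B3LYP,6-31G,0.9969,0.0594,0.0647,0.107
LSDA,6-31G,0.9965,0.0614,0.0691,0.115
HSEH1PBE,6-31G,0.9972,0.0554,0.0617,0.109
HCTH,6-31G,0.9966,0.0646,0.0681,0.0940
BPV86,6-31G,0.9970,0.0606,0.0643,0.0940
PBEPBE,6-31G,0.9945,0.0765,0.0870,0.161
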