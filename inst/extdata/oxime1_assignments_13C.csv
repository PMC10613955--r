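group_id,nucleus,atom_indices,delta_exp_ppm
C01,13C,1,167.21
C02,13C,2,131.68
C03,13C,3,124.69
C04,13C,4,75.46
C05,13C,5,56.04
C06,13C,6,50.29
C07,13C,7,50.25
C08,13C,8,49.77
C09,13C,9,42.31
C10,13C,10,40.48
C11,13C,11,40.46
C12,13C,12,40.38
C13,13C,13,39.10
C14,13C,14,37.18
C15,13C,15,34.82
C16,13C,16,31.14
C17,13C,17,27.53
C18,13C,18,27.29
C19,13C,19,25.79
C20,13C,20,25.42
C21,13C,21,24.80
C22,13C,22,22.86
C23,13C,23,22.56
C24,13C,24,21.80
C25,13C,25,19.03
C26,13C,26,17.75
C27,13C,27,17.13
C28,13C,28,16.34
C29,13C,29,15.92
C30,13C,30,15.40
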