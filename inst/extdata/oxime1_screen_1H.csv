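functional,basis_set,r_squared,rmse_ppm
B3LYP,6-31G,0.9915,0.108
LSDA,6-31G,0.9931,0.098
HSEH1PBE,6-31G,0.9915,0.108
HCTH,6-31G,0.9930,0.098
BPV86,6-31G,0.9926,0.101
PBEPBE,6-31G,0.9926,0.101
B3LYP,"6-31G(d,p)",0.9881,0.129
LSDA,"6-31G(d,p)",0.9897,0.12
HSEH1PBE,"6-31G(d,p)",0.9874,0.132
HCTH,"6-31G(d,p)",0.9886,0.126
BPV86,"6-31G(d,p)",0.9892,0.122
PBEPBE,"6-31G(d,p)",0.9889,0.124
B3LYP,"6-31+G(d,p)",0.9882,0.128
LSDA,"6-31+G(d,p)",0.9895,0.12
HSEH1PBE,"6-31+G(d,p)",0.9881,0.128
HCTH,"6-31+G(d,p)",0.9879,0.13
BPV86,"6-31+G(d,p)",0.9892,0.122
PBEPBE,"6-31+G(d,p)",0.9890,0.123
B3LYP,"6-31++G(d,p)",0.9838,0.219
LSDA,"6-31++G(d,p)",0.9855,0.142
HSEH1PBE,"6-31++G(d,p)",0.9848,0.146
HCTH,"6-31++G(d,p)",0.9813,0.161
BPV86,"6-31++G(d,p)",0.9843,0.148
PBEPBE,"6-31++G(d,p)",0.9841,0.149
B3LYP,"6-311G(d,p)",0.9865,0.137
LSDA,"6-311G(d,p)",0.9882,0.128
HSEH1PBE,"6-311G(d,p)",0.9866,0.136
HCTH,"6-311G(d,p)",0.9875,0.132
BPV86,"6-311G(d,p)",0.9880,0.129
PBEPBE,"6-311G(d,p)",0.9875,0.132
B3LYP,"6-31G(d,3p)",0.9864,0.137
LSDA,"6-31G(d,3p)",0.9878,0.13
HSEH1PBE,"6-31G(d,3p)",0.9863,0.138
HCTH,"6-31G(d,3p)",0.9875,0.132
BPV86,"6-31G(d,3p)",0.9879,0.13
PBEPBE,"6-31G(d,3p)",0.9876,0.131
B3LYP,"6-31G(3d,p)",0.9791,0.171
LSDA,"6-31G(3d,p)",0.9786,0.173
HSEH1PBE,"6-31G(3d,p)",0.9804,0.166
HCTH,"6-31G(3d,p)",0.9796,0.169
BPV86,"6-31G(3d,p)",0.9782,0.175
PBEPBE,"6-31G(3d,p)",0.9782,0.175
B3LYP,"6-31G(3d,3p)",0.9782,0.175
LSDA,"6-31G(3d,3p)",0.9775,0.178
HSEH1PBE,"6-31G(3d,3p)",0.9790,0.171
HCTH,"6-31G(3d,3p)",0.9756,0.185
BPV86,"6-31G(3d,3p)",0.9770,0.18
PBEPBE,"6-31G(3d,3p)",0.9769,0.18
B3LYP,cc-pVDZ,0.9856,0.141
LSDA,cc-pVDZ,0.9875,0.132
HSEH1PBE,cc-pVDZ,0.9851,0.144
HCTH,cc-pVDZ,0.9870,0.134
BPV86,cc-pVDZ,0.9876,0.131
PBEPBE,cc-pVDZ,0.9871,0.134
B3LYP,DGDZVP,0.9866,0.136
LSDA,DGDZVP,0.9890,0.124
HSEH1PBE,DGDZVP,0.9847,0.146
HCTH,DGDZVP,0.9871,0.134
BPV86,DGDZVP,0.9881,0.128
PBEPBE,DGDZVP,0.9877,0.13
B3LYP,DGDZVP2,0.9886,0.125
LSDA,DGDZVP2,0.9907,0.113
HSEH1PBE,DGDZVP2,0.9879,0.129
HCTH,DGDZVP2,0.9901,0.117
BPV86,DGDZVP2,0.9903,0.116
PBEPBE,DGDZVP2,0.9900,0.118
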