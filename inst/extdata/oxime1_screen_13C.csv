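functional,basis_set,r_squared,rmse_ppm
B3LYP,6-31G,0.9981,1.54
HSEH1PBE,6-31G,0.9988,1.24
B3PW91,6-31G,0.9985,1.37
CAM-B3LYP,6-31G,0.9990,1.16
mPW1PW91,6-31G,0.9988,1.24
wB97XD,6-31G,0.9989,1.2
B3LYP,"6-31G(d,p)",0.9983,1.5
HSEH1PBE,"6-31G(d,p)",0.9988,1.24
B3PW91,"6-31G(d,p)",0.9985,1.37
CAM-B3LYP,"6-31G(d,p)",0.9992,1.03
mPW1PW91,"6-31G(d,p)",0.9989,1.2
wB97XD,"6-31G(d,p)",0.9991,1.08
B3LYP,"6-31+G(d,p)",0.9987,1.31
HSEH1PBE,"6-31+G(d,p)",0.9990,1.12
B3PW91,"6-31+G(d,p)",0.9989,1.17
CAM-B3LYP,"6-31+G(d,p)",0.9991,1.06
mPW1PW91,"6-31+G(d,p)",0.9991,1.08
wB97XD,"6-31+G(d,p)",0.9987,1.27
B3LYP,"6-31++G(d,p)",0.9988,1.25
HSEH1PBE,"6-31++G(d,p)",0.9991,1.1
B3PW91,"6-31++G(d,p)",0.9990,1.13
CAM-B3LYP,"6-31++G(d,p)",0.9991,1.09
mPW1PW91,"6-31++G(d,p)",0.9990,1.13
wB97XD,"6-31++G(d,p)",0.9988,1.26
B3LYP,"6-311G(d,p)",0.9983,1.49
HSEH1PBE,"6-311G(d,p)",0.9986,1.36
B3PW91,"6-311G(d,p)",0.9984,1.43
CAM-B3LYP,"6-311G(d,p)",0.9989,1.18
mPW1PW91,"6-311G(d,p)",0.9987,1.3
wB97XD,"6-311G(d,p)",0.9988,1.24
B3LYP,"6-31G(d,3p)",0.9977,1.72
HSEH1PBE,"6-31G(d,3p)",0.9985,1.37
B3PW91,"6-31G(d,3p)",0.9982,1.51
CAM-B3LYP,"6-31G(d,3p)",0.9989,1.2
mPW1PW91,"6-31G(d,3p)",0.9986,1.32
wB97XD,"6-31G(d,3p)",0.9988,1.21
B3LYP,"6-31G(3d,p)",0.9930,3.01
HSEH1PBE,"6-31G(3d,p)",0.9951,2.51
B3PW91,"6-31G(3d,p)",0.9939,7.72
CAM-B3LYP,"6-31G(3d,p)",0.9963,2.19
mPW1PW91,"6-31G(3d,p)",0.9950,2.54
wB97XD,"6-31G(3d,p)",0.9976,1.76
B3LYP,"6-31G(3d,3p)",0.9899,3.61
HSEH1PBE,"6-31G(3d,3p)",0.9934,2.91
B3PW91,"6-31G(3d,3p)",0.9915,3.31
CAM-B3LYP,"6-31G(3d,3p)",0.9944,2.68
mPW1PW91,"6-31G(3d,3p)",0.9930,3.0
wB97XD,"6-31G(3d,3p)",0.9970,1.96
B3LYP,cc-pVDZ,0.9975,1.79
HSEH1PBE,cc-pVDZ,0.9983,1.48
B3PW91,cc-pVDZ,0.9980,1.6
CAM-B3LYP,cc-pVDZ,0.9989,1.2
mPW1PW91,cc-pVDZ,0.9985,1.4
wB97XD,cc-pVDZ,0.9989,1.19
B3LYP,DGDZVP,0.9989,1.19
HSEH1PBE,DGDZVP,0.9990,1.12
B3PW91,DGDZVP,0.9990,1.13
CAM-B3LYP,DGDZVP,0.9992,1.03
mPW1PW91,DGDZVP,0.9990,1.14
wB97XD,DGDZVP,0.9990,1.11
B3LYP,DGDZVP2,0.9981,1.57
HSEH1PBE,DGDZVP2,0.9987,1.31
B3PW91,DGDZVP2,0.9984,1.43
CAM-B3LYP,DGDZVP2,0.9992,1.03
mPW1PW91,DGDZVP2,0.9988,1.26
wB97XD,DGDZVP2,0.9990,1.12
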