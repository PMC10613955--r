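 Entering Gaussian System
 SCF Done:  E(RB3LYP) =  -1330.29948812     A.U. after   14 cycles
 Optimization completed.
 SCF Done:  E(RB3LYP) =  -1330.30176520     A.U. after    9 cycles
 Calculating GIAO nuclear magnetic shielding tensors.
 Magnetic shielding tensor (ppm):
      1  H    Isotropic =    31.1000   Anisotropy =     8.4016
   XX=    28.1485   YX=     1.1170   ZX=     0.5549
   XY=     1.0870   YY=    30.2489   ZY=     2.3211
   XZ=     0.6169   YZ=     2.3337   ZZ=    34.9026
      2  H    Isotropic =    25.2000   Anisotropy =    12.1593
   XX=    22.1821   YX=     0.9172   ZX=     0.1485
   XY=     0.8671   YY=    24.2092   ZY=     1.0283
   XZ=     0.3205   YZ=     1.2044   ZZ=    29.2087
      3  C    Isotropic =   187.9000   Anisotropy =    24.9232
   XX=   180.1101   YX=     3.2190   ZX=     1.0108
   XY=     2.9877   YY=   183.0902   ZY=     4.1272
   XZ=     1.2210   YZ=     4.0023   ZZ=   200.4997
 End of Minotr F.D. properties file
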