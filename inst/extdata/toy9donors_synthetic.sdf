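toy9donors
  synthetic test structure: 8 O + 1 N donors in 3D, no exact symmetry

 12 11  0  0  0  0  0  0  0  0999 V2000
    2.1130    0.0210   -0.0340 O  0  0  0  0  0  0  0  0  0  0  0  0
   -2.0870    0.0440    0.0180 O  0  0  0  0  0  0  0  0  0  0  0  0
    0.0310    2.0920    0.0270 O  0  0  0  0  0  0  0  0  0  0  0  0
   -0.0120   -2.1430    0.0510 O  0  0  0  0  0  0  0  0  0  0  0  0
    0.0420   -0.0330    2.1200 O  0  0  0  0  0  0  0  0  0  0  0  0
   -0.0270    0.0160   -2.0950 O  0  0  0  0  0  0  0  0  0  0  0  0
    3.2140    1.0920    0.0330 O  0  0  0  0  0  0  0  0  0  0  0  0
   -3.1870    1.1230   -0.0420 O  0  0  0  0  0  0  0  0  0  0  0  0
    0.0240    3.2050    1.1410 N  0  0  0  0  0  0  0  0  0  0  0  0
    4.0000    0.0000    0.0000 C  0  0  0  0  0  0  0  0  0  0  0  0
   -4.0000    0.0000    0.0000 C  0  0  0  0  0  0  0  0  0  0  0  0
    0.0000    4.0000    0.0000 C  0  0  0  0  0  0  0  0  0  0  0  0
  1 10  1  0  0  0  0
  7 10  1  0  0  0  0
  2 11  1  0  0  0  0
  8 11  1  0  0  0  0
  3 12  1  0  0  0  0
  9 12  1  0  0  0  0
  4 10  1  0  0  0  0
  5 12  1  0  0  0  0
  6 11  1  0  0  0  0
 10 11  1  0  0  0  0
 11 12  1  0  0  0  0
M  END
$$$$
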