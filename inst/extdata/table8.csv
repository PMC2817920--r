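species,area_A2,volume_A3,dipole_debye,dv,abl_A,energy_J,asf_best,asf_mean
Fe-Hali,949.7,1065.0,8.82,0.0110,2.627,6307365,-0.0000634,0.000253
Fe-Hali-H2O,991.7,1087.2,13.83,0.0126,2.483,3946000,0.00000086,-5.77e-8
Hali,1036.5,1071.7,2.48,0.0023,,1491027,,
Fe-Disco,656.4,650.6,6.48,0.0100,2.231,1787000,0.0000153,0.00389
Fe-Disco_H2O,697.2,673.2,10.68,0.0159,2.211,1090000,0.00000686,0.0000281
Disco,689.9,650.9,4.84,0.0074,,135515,,
Fe-Kah,1537.0,1546.6,15.99,0.0103,2.283,2005200,0.00001246,0.00156
Fe-Kah-H2O,1565.9,1565.1,19.04,0.0121,2.325,1551000,0.00001988,0.000003406
Kah,1584.3,1548.0,4.82,0.0031,,853007,,
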