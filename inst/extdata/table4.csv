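complex_id,donors,dipole_debye,d1,d2,d3,d4,d5,d6,area_A2,volume_A3,molar_mass,energy_J,charge,printed_abl,printed_dv,printed_asf
Hali-01,1;2;3;5;6;7,13.87,2.639,2.647,2.574,2.453,2.684,2.706,945.71,1060.93,1167.57,3674624,1,2.617,0.01307,6.9e-5
Hali-02,3;5;6;7;9;10,19.67,2.540,2.488,2.664,2.710,2.697,2.727,1030.39,1080.05,1167.57,7393466,1,2.194,0.01821,8.0e-5
Hali-03,1;3;5;6;7;9,15.91,2.682,2.540,2.462,2.695,2.710,2.683,941.03,1069.44,1167.57,6085918,1,2.629,0.09596,1.0e-4
Hali-04,1;2;3;6;7;10,19.94,2.717,2.718,2.664,2.730,2.680,2.686,893.96,1051.35,1167.57,-4685181,1,2.699,0.01897,-6.3e-5
Hali-05,2;5;7;9;10;12,7.55,2.729,2.769,2.750,2.782,2.592,2.729,930.78,1057.96,1167.57,6953.642,1,2.720,0.00714,2.5e-7
Hali-06,1;3;5;6;7;10,18.78,2.673,2.528,2.526,2.725,2.728,,1016.45,1076.59,1167.57,7292712,1,2.649,0.01744,1.0e-4
Hali-07,2;3;5;6;7;14,8.60,2.724,2.482,2.586,2.710,2.719,2.772,887.65,1046.50,1167.57,1394772,1,2.666,0.00822,4.3e-5
Hali-08,14;15;16;17;18;19,11.75,2.687,1.886,2.614,2.318,2.219,1.999,1027.22,1076.81,1166.57,2559699,1,2.287,0.01091,5.0e-5
Hali-09,1;14;16;17;18;19,11.31,2.634,2.692,2.699,2.401,2.084,1.946,976.65,1065.90,1166.60,3294402,1,2.416,0.01061,7.0e-5
Hali-10,1;15;16;17;18;19,10.84,2.613,2.502,2.616,2.103,2.255,1.984,991.43,1071.33,1166.57,3577592,1,2.059,0.01012,6.8e-5
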