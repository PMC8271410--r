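run,A,D,F,G,plant_kj_mol,microbe_kj_mol
0,0,0,0,0,-39.964,-10.186
1,0,1,0,1,,-26.891
2,0,0,1,0,,
3,0,1,1,0,,-5.009
4,1,1,0,0,-15.999,
5,1,0,0,1,-45.742,
6,1,0,1,1,-64.551,-28.054
7,1,0,1,0,-63.956,
8,1,1,0,1,-25.355,-14.909
9,0,1,1,1,-61.141,
10,0,0,0,1,-69.743,-21.361
11,0,0,1,1,-28.668,
12,0,1,0,0,-42.800,
13,1,1,1,1,-92.927,-20.589
14,1,1,1,0,,-18.142
15,1,0,0,0,-81.088,-40.632
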