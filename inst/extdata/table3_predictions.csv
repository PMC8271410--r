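molecule_id,CM,CM_rel_err_pct,PM,PM_rel_err_pct,MM,MM_rel_err_pct
BDEs-3,74.645,,54.702,,53.951,
BDEs-3-1,90.157,20.78,60.395,10.41,59.704,10.66
BDEs-3-2,75.509,1.16,61.094,11.69,68.707,27.35
BDEs-3-3,95.499,27.94,51.523,-5.81,70.958,31.52
BDEs-3-4,96.828,29.72,57.677,5.44,63.680,18.03
BDEs-3-5,95.060,27.35,57.280,4.71,62.087,15.08
BDEs-3-6,77.446,3.75,55.847,2.09,61.235,13.50
BDEs-3-7,104.713,40.28,63.826,16.68,72.277,33.97
BDEs-3-8,106.414,42.56,58.210,6.41,63.680,18.03
BDEs-3-9,81.846,9.65,59.429,8.64,72.444,34.28
BDEs-3-10,107.399,43.88,57.810,5.68,62.087,15.08
BDEs-3-11,65.464,-12.30,65.013,18.85,73.961,37.09
BDEs-3-12,32.885,-55.94,61.518,12.46,70.469,30.62
BDEs-3-13,100.231,34.28,60.395,10.41,63.096,16.95
BDEs-3-14,30.409,-59.26,45.082,-17.59,51.880,-3.84
BDEs-3-15,30.409,-59.26,45.082,-17.59,51.880,-3.84
BDEs-3-16,30.409,-59.26,45.082,-17.59,51.880,-3.84
BDEs-3-17,30.409,-59.26,45.082,-17.59,51.880,-3.84
BDEs-3-18,30.409,-59.26,45.082,-17.59,51.880,-3.84
BDEs-3-19,90.910,21.79,68.479,25.19,68.345,26.68
BDEs-3-20,30.409,-59.26,45.082,-17.59,51.880,-3.84
BDEs-3-21,30.409,-59.26,45.082,-17.59,51.880,-3.84
BDEs-3-22,30.409,-59.26,45.082,-17.59,51.880,-3.84
BDEs-3-23,30.409,-59.26,45.082,-17.59,51.880,-3.84
BDEs-3-24,30.409,-59.26,45.082,-17.59,51.880,-3.84
BDEs-3-25,30.409,-59.26,45.082,-17.59,51.880,-3.84
BDEs-3-26,30.409,-59.26,45.082,-17.59,51.880,-3.84
BDEs-3-27,30.409,-59.26,45.082,-17.59,51.880,-3.84
BDEs-3-28,30.409,-59.26,45.082,-17.59,51.880,-3.84
BDEs-3-29,30.409,-59.26,45.082,-17.59,51.880,-3.84
BDEs-3-30,84.333,12.98,54.200,-0.92,64.863,20.23
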