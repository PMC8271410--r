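molecule_id,cbr_bde_kcal_mol,cbr_rel_err_pct,ec50_mg_l,ec50_rel_err_pct,log_bcf,bcf_rel_err_pct,vp_pa,vp_rel_err_pct,insoluble
BDEs-3,95.378,,0.799,,5.91,,0.109,,0
BDEs-3-1,95.965,0.61,11.362,,0.50,-91.54,1.68e-5,-99.98,1
BDEs-3-2,95.630,0.26,1620.691,,0.50,-91.54,9.30e-10,-100.00,1
BDEs-3-4,96.191,0.85,0.353,-55.82,3.29,-44.33,1.07e-2,-90.18,0
BDEs-3-5,96.199,0.86,0.170,-78.72,3.61,-38.92,3.81e-3,-96.50,0
BDEs-3-6,96.215,0.88,0.092,-88.49,3.89,-34.18,2.74e-3,-97.49,0
BDEs-3-7,96.264,0.93,0.047,-94.12,4.19,-29.10,1.26e-3,-98.84,0
BDEs-3-8,96.258,0.92,0.992,24.16,2.32,-60.74,6.34e-4,-99.42,0
BDEs-3-9,96.090,0.75,2.029,153.94,2.61,-55.84,2.67e-4,-99.76,0
BDEs-3-10,96.357,1.03,1.609,101.38,2.68,-54.65,1.48e-3,-98.64,0
BDEs-3-13,96.027,0.68,0.573,-28.29,3.10,-47.55,2.30e-3,-97.89,0
BDEs-3-19,95.785,0.43,0.417,-47.81,2.82,-52.28,3.52e-4,-99.68,0
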