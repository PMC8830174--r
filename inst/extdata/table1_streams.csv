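plant,role,ts_pct,vs_pct_ts,vs_red_pct,ph,nh4_n_g_per_kg,nh3_n_g_per_kg,vfa_mg_per_l
FW1,digester,5.3,73.6,70,7.8,3.4,0.34,80
FW1,post-digester,4.3,71.5,77,7.8,3.6,0.35,40
FW2,digester,3.9,66.7,48,7.9,3.6,0.31,1360
FW2,post-digester,3.8,65.5,50,7.9,3.8,0.35,190
FW3,digester,4.1,69.6,75,7.5,2.4,0.10,40
FW3,post-digester,3.8,67.9,77,7.7,2.5,0.13,20
FW-TD,digester,11.6,66.6,65,7.8,3.8,0.74,8450
AW1,digester,10,88.2,67,7.6,2.4,0.12,150
AW1,post-digester,7.2,86.0,78,7.5,2.3,0.08,60
AW2,digester,8.6,81.8,66,7.3,3.3,0.09,320
AW2,post-digester,6.3,77.3,77,7.8,2.4,0.20,2
AWM-A,digester,7.3,74.1,62,7.9,2.0,0.18,370
AWM-B,digester,7.4,74.2,62,7.8,3.4,0.26,420
WWTP1,digester,3.2,66.5,55,7.9,1.4,0.15,20
WWTP2-A,digester,1.6,64.5,63,7.2,0.8,0.02,20
WWTP2-B,digester,1.7,65.7,61,7.4,0.9,0.02,40
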