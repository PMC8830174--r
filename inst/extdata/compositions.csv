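plant,role,vs_g_per_kg,protein_pct_vs,fat_pct_vs,carbohydrates_pct_vs,hemicellulose_pct_vs,cellulose_pct_vs,free_sugars_pct_vs,lignin_pct_vs,protein_g_per_kg,protein_total_g_per_kg,vfa_acetate_mmol_per_l
FW1,substrate,120,22,32,39,10,12,16,8,27,NA,55
FW1,digester,NA,NA,NA,NA,NA,NA,NA,NA,17,NA,NA
FW1,post-digester,NA,NA,NA,NA,NA,NA,NA,NA,7,12,NA
FW-TD,substrate,180,20,11,52,15,NA,NA,NA,NA,NA,NA
FW-TD,digester,NA,NA,NA,NA,NA,NA,NA,NA,14.6,21.1,NA
WWTP2-A,substrate,27,29,17,43,14,9,20,10,NA,NA,NA
WWTP2-B,substrate,28,30,15,46,14,10,22,10,NA,NA,NA
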