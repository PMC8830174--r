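plant,stage,role,olr_kgvs_m3_day,hrt_days,temperature_c
FW1,1,digester,4.2,35,42
FW1,2,post-digester,NA,20,41
FW2,1,digester,3.0,30,37
FW2,2,post-digester,NA,5,37
FW3,1,digester,3.8,27,38
FW3,2,post-digester,NA,7,36
FW-TD,1,digester,4.7,27,55
AW1,1,digester,5.8,55,38
AW1,2,post-digester,NA,40,38
AW2,1,digester,3.1,40,38
AW2,2,post-digester,NA,45,38
AWM-A,1,digester,3.4,55,38
AWM-B,1,digester,3.4,55,38
WWTP1,1,digester,2.5,20,38
WWTP2-A,1,digester,1.5,17,37
WWTP2-B,1,digester,1.8,15,37
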