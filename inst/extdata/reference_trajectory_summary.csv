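trajectory,orientation,ilium_cortical_mean,ilium_cortical_sd,ilium_cancellous_mean,ilium_cancellous_sd,ilium_total_mean,ilium_total_sd,ilium_bone_fraction_mean,ilium_bone_fraction_sd,sacrum_cortical_mean,sacrum_cortical_sd,sacrum_cancellous_mean,sacrum_cancellous_sd,sacrum_total_mean,sacrum_total_sd,sacrum_bone_fraction_mean,sacrum_bone_fraction_sd,gap_mean_mm,gap_sd_mm
PL1,posterolateral,296,393,2926,1301,12415,1843,0.25,0.11,23,39,923,401,5838,1165,0.16,0.07,6.53,0.69
PL2,posterolateral,109,138,2436,774,10778,2713,0.24,0.06,53,62,1276,418,7165,1725,0.19,0.07,3.79,0.49
top,lateral,767,340,2314,485,7801,1554,0.40,0.10,103,129,1818,545,15415,1805,0.12,0.03,1.50,0.29
middle,lateral,977,278,3075,809,10072,1212,0.41,0.11,44,52,1132,401,5998,1360,0.20,0.07,1.21,0.21
bottom,lateral,766,353,2512,753,8042,1260,0.41,0.10,44,54,1069,283,9040,1761,0.12,0.03,1.63,0.31
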