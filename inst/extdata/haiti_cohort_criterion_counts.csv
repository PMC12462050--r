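criterion,overall,mets_h,mets_1,mets_2,mets_3
total,2721,578,611,616,603
e_bp,1061,479,611,588,562
on_antihypertensive,336,184,227,272,247
e_wc,1223,524,611,518,492
e_glu_fasting,293,214,142,152,145
e_glu_nonfasting,26,165,17,21,18
low_hdl,1106,472,334,319,306
e_tg,366,258,145,148,143
hospitalized_cvd,29,16,14,16,13
pmh,706,334,395,517,478
fh,1185,290,312,438,434
smoke_or_alcohol,276,36,37,37,93
high_fat,2363,464,486,496,552
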