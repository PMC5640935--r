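quantity,count
cohort_total,5061
metastasized,1598
bone_only_first,413
visceral_only_first,747
bone_and_visceral_first,438
pairs_V,246
pairs_BV,258
pairs_B,238
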