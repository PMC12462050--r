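index_name,reference_name,tp,fp,fn,tn
MetS-1,MetS-H,430,181,148,1962
MetS-2,MetS-H,375,241,203,1902
MetS-3,MetS-H,352,251,226,1892
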