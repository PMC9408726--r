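region,n_days,study_hw_days,nws_hw_days,overlap_days
Coastal,704,190,26,24
Piedmont,719,241,18,17
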