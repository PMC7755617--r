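metric,lo,hi,n
lr_vol_ratio_pct,88.9,110.6,111
lr_qt2_ratio_pct,93.7,104.2,111
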