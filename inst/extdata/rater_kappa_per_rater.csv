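group,rater,without_report,with_report
experts,1a,0.86,0.82
experts,1b,0.93,0.96
experts,1c,0.78,0.96
trainees,2a,0.86,0.82
trainees,2b,0.69,0.80
trainees,2c,0.66,0.74
analysts,3a,0.74,0.93
analysts,3b,0.30,0.78
analysts,3c,0.93,0.96
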