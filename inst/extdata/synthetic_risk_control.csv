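time_months,n_at_risk
0,250
12,226
24,206
36,193
48,174
60,164
72,148
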