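time_months,survival
0,1
3,0.9766
6,0.9685
9,0.9577
12,0.9444
15,0.9188
18,0.9029
21,0.8997
24,0.8863
27,0.8741
30,0.8684
33,0.8596
36,0.8511
39,0.827
42,0.827
45,0.8175
48,0.8038
51,0.8038
54,0.8024
57,0.7967
60,0.7933
63,0.7782
66,0.7608
69,0.7526
72,0.7483
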