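level_percent,n_tested,n_detected
1.160,9,9
0.580,9,9
0.290,9,9
0.145,9,8
0.073,9,4
0.036,9,0
0.018,9,0
0.009,9,0
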