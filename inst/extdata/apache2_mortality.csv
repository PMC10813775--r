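score_min,score_max,mortality_pct
0,4,4
5,9,8
10,14,15
15,19,25
20,24,40
25,29,55
30,34,75
35,71,85
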