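plant_id,side,raw_count
1,a,54
1,b,96
2,a,75
2,b,147
3,a,47
3,b,152
4,a,76
4,b,183
5,a,163
5,b,0
6,a,102
6,b,157
7,a,89
7,b,85
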