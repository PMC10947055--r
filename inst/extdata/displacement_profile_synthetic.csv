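eccentricity_deg,displacement_deg
0,0
0.5,1.15
1,1.85
1.5,2.15
2,2.1
2.5,1.9
3,1.65
4,1.2
5,0.85
6,0.55
8,0.2
10,0.05
12,0
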