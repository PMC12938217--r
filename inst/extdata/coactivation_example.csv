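network,pre,group1,group2
1,0.65,0.90,2.50
2,0.75,2.45,2.45
3,21.35,52.25,47.15
4,1.30,2.30,1.95
5,0.20,0.55,0.30
6,2.65,4.85,3.30
7,1.10,1.20,47.90
8,0.60,1.50,1.75
9,3.10,2.85,2.35
10,0.80,1.50,1.55
11,3.80,5.45,4.20
12,0.75,0.45,1.10
13,0.05,0.00,0.00
14,0.40,0.95,0.95
15,2.35,38.70,3.70
16,0.90,2.20,2.60
17,0.20,0.80,0.60
18,1.05,1.20,2.00
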