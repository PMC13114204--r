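patient,marked,detected,sensitivity,fdr_per_hour
1,6,6,100.00,0.02
2,2,2,100.00,0.23
3,6,6,100.00,0.32
4,3,3,100.00,0.22
5,4,4,100.00,0.03
6,6,6,100.00,3.30
7,2,2,100.00,0.10
8,4,4,100.00,0.65
9,3,3,100.00,0.01
10,5,5,100.00,0.02
11,2,2,100.00,0.00
12,23,23,100.00,1.70
13,8,7,87.50,0.76
14,7,7,100.00,2.54
15,19,19,100.00,0.20
16,2,2,100.00,10.65
17,2,2,100.00,0.05
18,5,4,80.00,0.06
19,2,2,100.00,0.00
20,7,7,100.00,0.62
21,3,3,100.00,0.03
22,2,2,100.00,0.00
23,6,6,100.00,0.11
24,15,15,100.00,1.08
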