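patient,sensitivity,specificity,accuracy
1,100.00,99.71,99.71
2,100.00,99.72,99.72
3,100.00,99.07,99.07
4,100.00,97.56,97.56
5,100.00,99.95,99.95
6,100.00,96.99,96.99
7,100.00,99.92,99.92
8,94.27,95.14,95.09
9,100.00,100.00,100.00
10,100.00,99.97,99.97
11,100.00,99.92,99.92
12,98.32,97.31,97.24
13,81.11,98.19,98.14
14,100.00,96.70,96.70
15,98.97,98.86,98.85
16,100.00,91.34,91.29
17,100.00,99.92,99.92
18,87.50,99.70,99.67
19,100.00,99.92,99.92
20,98.63,97.10,97.04
21,100.00,99.85,99.85
22,100.00,99.99,99.99
23,100.00,99.70,99.70
24,92.65,98.28,98.24
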