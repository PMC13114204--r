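patient,sensitivity,specificity,accuracy
1,81.58,99.22,99.06
2,73.05,83.57,83.50
3,88.58,97.01,96.67
4,95.24,96.85,96.79
5,85.90,99.75,97.35
6,87.38,99.82,96.74
7,89.96,93.05,92.89
8,95.08,99.94,95.66
9,100.00,99.95,99.79
10,84.17,89.77,87.16
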