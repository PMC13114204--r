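patient,marked,detected,sensitivity,fdr_per_hour
1,18,12,66.67,0.28
2,10,7,70.00,1.98
3,9,9,100.00,0.19
4,9,8,88.89,1.67
5,19,19,100.00,0.14
6,8,6,87.50,0.08
7,28,28,100.00,1.42
8,37,37,100.00,0.06
9,2,2,100.00,0.00
10,3,3,100.00,0.41
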