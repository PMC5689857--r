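# Per-configuration pristine Bragg peak commissioning comparison:
# absolute PDD(0.5) difference (%), measured and simulated D90 (cm),
# and their signed difference (measured - simulated) as printed in the
# commissioning report tables.
config,group,pdd05_diff,d90_measured,d90_simulated,d90_diff
1,large,0.8,25.10,25.06,0.04
2,large,0.8,22.59,22.54,0.05
3,large,0.4,20.92,20.87,-0.05
4,large,0.5,18.78,18.71,0.07
5,large,1.1,16.80,16.74,0.06
6,large,1.5,14.94,14.90,0.04
7,large,1.0,13.24,13.19,0.05
8,large,0.6,11.52,11.61,-0.09
9,large,1.2,10.07,10.02,0.05
10,large,0.5,8.72,8.63,0.09
11,large,1.5,7.39,7.31,0.08
12,large,1.3,6.67,6.58,0.09
13,deep,1.2,31.88,31.84,0.04
14,deep,0.6,29.51,29.51,0.00
15,deep,1.6,27.08,27.06,0.02
16,deep,1.8,24.55,24.52,0.03
17,deep,1.1,22.06,22.02,0.04
18,small,1.5,20.05,20.00,0.05
19,small,1.9,17.81,17.74,0.07
20,small,0.3,15.39,15.32,0.07
21,small,1.5,13.32,13.30,0.02
22,small,1.7,11.28,11.24,0.04
23,small,0.6,9.18,9.18,0.00
24,small,1.2,7.12,7.12,0.00
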