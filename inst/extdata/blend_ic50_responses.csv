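run,x1,x2,x3,ic50_glucosidase,ic50_amylase
1,1,0,0,0.068 ± 0.003,0.047 ± 0.008
2,0,1,0,0.078 ± 0.008,0.067 ± 0.004
3,0,0,1,0.045 ± 0.002,0.034 ± 0.004
4,0.5,0.5,0,0.044 ± 0.001,0.022 ± 0.003
5,0.5,0,0.5,0.043 ± 0.005,0.055 ± 0.006
6,0,0.5,0.5,0.047 ± 0.001,0.047 ± 0.002
7,0.333,0.333,0.333,0.045 ± 0.002,0.152 ± 0.007
8,0.333,0.333,0.333,0.047 ± 0.003,0.15 ± 0.003
9,0.333,0.333,0.333,0.045 ± 0.009,0.161 ± 0.008
10,0.667,0.167,0.167,0.053 ± 0.006,0.09 ± 0.006
11,0.167,0.667,0.167,0.052 ± 0.001,0.1 ± 0.004
12,0.167,0.167,0.667,0.043 ± 0.002,0.09 ± 0.003
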