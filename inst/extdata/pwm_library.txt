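>SBE_CAGAC 5
0.02 0.90 0.02 0.90 0.02
0.90 0.04 0.02 0.04 0.90
0.04 0.04 0.92 0.04 0.04
0.04 0.02 0.04 0.02 0.04
>E2F_like 8
0.05 0.05 0.05 0.05 0.05 0.05 0.80 0.05
0.05 0.85 0.05 0.85 0.80 0.05 0.05 0.80
0.85 0.05 0.85 0.05 0.10 0.85 0.10 0.10
0.05 0.05 0.05 0.05 0.05 0.05 0.05 0.05
>AP1_like 7
0.05 0.05 0.80 0.80 0.05 0.10 0.80
0.05 0.05 0.10 0.05 0.80 0.05 0.05
0.10 0.80 0.05 0.10 0.05 0.05 0.10
0.80 0.10 0.05 0.05 0.10 0.80 0.05
>uniform_ctrl 6
0.25 0.25 0.25 0.25 0.25 0.25
0.25 0.25 0.25 0.25 0.25 0.25
0.25 0.25 0.25 0.25 0.25 0.25
0.25 0.25 0.25 0.25 0.25 0.25
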