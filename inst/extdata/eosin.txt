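# Eosinophil counts, N = 42, reported bounds "<3" and "<4"
# assumed family: poisson (censored means count <= bound - 1)
<3
<3
<3
<3
<3
<3
<3
<3
<3
<3
<3
<4
<4
<4
<4
<4
<4
<4
<4
<4
<4
<4
3
3
3
3
3
3
4
4
5
5
5
6
6
6
6
6
7
7
8
12
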