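# Uric acid concentrations (mg/dl), N = 42, two LLOQs (5.0, 5.5)
# assumed family: normal
<5.0
<5.0
<5.0
<5.0
<5.0
<5.0
<5.0
<5.0
<5.0
<5.5
<5.5
<5.5
<5.5
<5.5
<5.5
<5.5
<5.5
<5.5
<5.5
<5.5
<5.5
<5.5
<5.5
5.0
5.1
5.7
5.7
5.7
5.8
5.8
6.0
6.1
6.3
6.3
6.4
6.5
6.6
6.7
6.7
6.8
7.0
7.3
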