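# Ferritin concentrations (ng/ml), N = 42, two LLOQs (80, 100)
# assumed family: exponential
<80
<80
<80
<80
<80
<80
<80
<80
<80
<100
<100
<100
<100
<100
<100
<100
<100
<100
<100
<100
<100
<100
<100
84.4
88.2
106.0
108.0
117.0
140.0
144.0
170.0
185.0
209.0
262.0
295.0
103.0
104.0
106.0
112.0
181.0
280.0
355.0
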