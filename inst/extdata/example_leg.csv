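level_cm,circumference_cm
0,58.5
5,56.0
10,54.0
15,52.5
20,50.0
25,47.5
30,44.0
35,41.0
40,38.5
45,36.5
50,35.0
55,34.0
60,32.5
65,29.0
70,25.5
75,23.0
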