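time,status
22.5,1
37.5,1
46,1
48.5,1
51.5,1
53,1
54.5,1
57.5,1
66.5,1
68,1
69.5,1
76.5,1
77,1
78.5,1
80,1
81.5,1
82,1
83,1
84,1
91.5,1
93.5,1
102.5,1
107,1
108.5,1
112.5,1
113.5,1
116,1
117,1
118.5,1
119,1
120,1
122.5,1
123,1
127.5,1
131,1
132.5,1
134,1
135,0
135,0
135,0
135,0
135,0
135,0
135,0
135,0
135,0
135,0
135,0
135,0
135,0
135,0
135,0
135,0
135,0
135,0
135,0
135,0
135,0
135,0
135,0
135,0
135,0
135,0
135,0
135,0
135,0
135,0
135,0
135,0
135,0
135,0
135,0
135,0
135,0
135,0
135,0
135,0
135,0
135,0
135,0
135,0
135,0
135,0
135,0
135,0
135,0
135,0
135,0
135,0
135,0
135,0
135,0
135,0
135,0
135,0
135,0
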