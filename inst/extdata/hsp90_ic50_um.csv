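compound_id,ic50_um,group
15,0.153,A
16,0.184,A
18,0.130,A
19,0.074,A
20,0.037,A
21,0.085,A
22,0.167,A
24,0.160,A
26,0.055,B
27,0.041,B
28,0.190,B
30,0.240,B
46,0.026,B
57,0.084,B
58,0.022,B
59,0.250,B
61,0.040,B
64,0.260,B
65,0.048,B
66,0.062,B
69,0.020,B
73,0.040,B
81a,0.230,C
81b,0.430,C
81c,0.620,C
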