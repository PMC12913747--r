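# provenance: reference (published cohort estimate, year 0 to 1)
state,0-0.099,0.1-0.199,0.2-0.299,0.3-0.399,0.4-0.499,0.5-0.599,0.6-0.699,0.7-0.799,0.8-0.899,0.9-1
0-0.099,0,0,0,0,0,0,0,0,0,0
0.1-0.199,0,0,0,0,0,0,0,0,0,0
0.2-0.299,0,0,0,0,0,0,0,0,0,0
0.3-0.399,0,0,0,0,0,0,0,0,0,0
0.4-0.499,0,0,0,0,0,0.25,0.25,0,0.25,0.25
0.5-0.599,0,0,0,0,0,0,0,0,0,0
0.6-0.699,0,0,0,0,0,0,0,0.17,0.17,0.67
0.7-0.799,0,0,0,0,0,0,0,0.25,0.25,0.5
0.8-0.899,0,0,0,0,0,0,0.03,0.03,0.22,0.72
0.9-1,0,0,0,0,0,0,0,0.024,0.12,0.86
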