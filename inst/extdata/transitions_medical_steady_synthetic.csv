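# provenance: synthetic (invented long-run medical decline dynamics; not published data)
state,0-0.099,0.1-0.199,0.2-0.299,0.3-0.399,0.4-0.499,0.5-0.599,0.6-0.699,0.7-0.799,0.8-0.899,0.9-1
0-0.099,0.9,0.1,0,0,0,0,0,0,0,0
0.1-0.199,0.2,0.7,0.1,0,0,0,0,0,0,0
0.2-0.299,0,0.2,0.7,0.1,0,0,0,0,0,0
0.3-0.399,0,0,0.2,0.7,0.1,0,0,0,0,0
0.4-0.499,0,0,0,0.2,0.7,0.1,0,0,0,0
0.5-0.599,0,0,0,0,0.2,0.7,0.1,0,0,0
0.6-0.699,0,0,0,0,0,0.2,0.7,0.1,0,0
0.7-0.799,0,0,0,0,0,0,0.2,0.7,0.1,0
0.8-0.899,0,0,0,0,0,0,0,0.2,0.7,0.1
0.9-1,0,0,0,0,0,0,0,0,0.2,0.8
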