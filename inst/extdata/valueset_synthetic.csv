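# provenance: synthetic (stand-in additive EQ-5D-3L tariff; not a published national value set)
domain,level,decrement
mo,1,0
mo,2,0.07
mo,3,0.31
sc,1,0
sc,2,0.10
sc,3,0.34
ua,1,0
ua,2,0.04
ua,3,0.21
pd,1,0
pd,2,0.12
pd,3,0.39
ad,1,0
ad,2,0.09
ad,3,0.26
intercept,,0
floor,,-0.11
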