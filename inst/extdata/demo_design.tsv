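sample_id	condition	replicate
p1	plusUV	1
p2	plusUV	2
m1	minusUV	1
m2	minusUV	2
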