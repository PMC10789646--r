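accession	name	symbol
Q12906	ILF3	ILF3
Q15366	PCBP2	PCBP2
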