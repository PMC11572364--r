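Gene	Start	End	Length (bp)	Aminoacid	Start/Stop codon	Intergenic region (bp)	Strand
trnI(gau)	1	73	73	–	–	67	H
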