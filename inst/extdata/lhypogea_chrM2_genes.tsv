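Gene	Start	End	Length (bp)	Aminoacid	Start/Stop codon	Intergenic region (bp)	Strand
ND4L	1	291	291	96	AUG/UAG	0	H
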