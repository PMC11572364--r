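Gene	Start	End	Length (bp)	Aminoacid	Start/Stop codon	Intergenic region (bp)	Strand
rnl	1	2,526	2,526	–	–	223	H
trnI(cau)	3,124	3,195	72	–	–	597	H
trnF(gaa)	3,394	3,465	72	–	–	198	H
ND4	3,546	5,006	1,461	486	AUG/UAA	80	H
trnV(uac)	5,994	6,064	71	–	–	987	H
trnR(ucg)	7,173	7,243	71	–	–	1,108	H
trnS(uga)	7,670	7,740	71	–	–	426	H
trnC(gca)	8,333	8,405	73	–	–	592	H
trnK(uuu)	10,197	10,269	73	–	–	1,791	H
ATP8	10,271	10,486	216	71	AUG/UAG	1	H
trnH(gug)	10,553	10,625	73	–	–	66	H
COX3	10,729	11,541	813	270	AUG/UAA	103	H
trnW(uca)	11,762	11,832	71	–	–	220	H
ATP9	13,413	13,649	237	78	GUG/UAA	1,580	H
trnN(guu)	13,654	13,724	71	–	–	4	H
CYTB	13,726	14,871	1,146	381	AUG/UAA	1	H
trnA(ugc)	14,981	15,052	72	–	–	109	H
COX2	15,062	15,793	732	243	AUG/UAA	9	H
trnD(guc)	15,814	15,884	71	–	–	20	H
ND3	15,896	16,255	360	119	AUG/UAA	11	H
trnS(gcu)	17,185	17,257	73	–	–	929	H
trnP(ugg)	18,754	18,824	71	–	–	1,496	H
rns	18,827	20,023	1,197	–	–	2	H
trnG(ucc)	20,025	20,096	72	–	–	1	H
trnQ(uug)	20,099	20,171	73	–	–	2	H
ATP6	20,173	20,892	720	239	AUG/UAA	1	H
trnE(uuc)	20,960	21,030	71	–	–	67	H
ND6	21,040	21,579	540	179	GUG/UAA	9	H
COX1	21,939	23,501	1,563	520	GUG/UAG	359	H
ND5	23,502	25,340	1,839	612	AUG/UAA	0	H
ND2	25,572	26,936	1,365	454	AUG/UAA	231	H
trnL(uag)	27,308	27,380	73	–	–	371	H
ND1	29,090	30,043	954	317	AUG/UAA	1,709	H
trnY(gua)	30,805	30,876	72	–	–	761	H
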