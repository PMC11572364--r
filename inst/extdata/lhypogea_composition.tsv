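region	G	A	T	C	GC_pct	AT_skew	GC_skew	length_bp
atp6	22.4	23.2	39.4	15.0	37.4	-0.2594	0.1970	720
atp8	26.4	21.8	33.3	18.5	44.9	-0.2101	0.1753	216
atp9	26.6	24.5	31.2	17.7	44.3	-0.1212	0.2000	237
cox1	23.0	24.1	38.2	14.8	37.7	-0.2271	0.2169	1563
cox2	20.9	28.8	36.5	13.8	34.7	-0.1172	0.2047	732
cox3	22.8	23.7	38.5	15.0	37.8	-0.2372	0.2052	813
cytb	20.5	25.2	40.8	13.4	33.9	-0.2365	0.2082	1146
nd1	24.7	23.3	38.6	13.4	38.2	-0.2475	0.2967	954
nd2	23.5	23.7	38.1	14.7	38.2	-0.2322	0.2322	1365
nd3	23.1	24.7	41.9	10.3	33.3	-0.2583	0.3833	360
nd4	22.5	22.8	41.8	12.9	35.4	-0.2945	0.2689	1461
nd4l	33.0	21.3	32.7	13.1	46.1	-0.2102	0.4328	291
nd5	21.6	24.7	39.8	13.8	35.5	-0.2334	0.2209	1839
nd6	22.4	24.6	42.0	10.9	33.3	-0.2611	0.3444	540
rnl	22.7	33.0	31.1	13.2	35.9	0.0303	0.2657	2526
rns	24.8	32.8	30.8	11.5	36.3	0.0315	0.3655	1197
tRNAs	24.2	28.1	32.1	15.5	39.8	-0.0668	0.2192	1366
IGRs	24.5	24.8	35.2	15.6	40.0	-0.1725	0.2223	14064
chrM1	23.6	25.7	36.1	14.6	38.2	-0.1677	0.2362	31099
chrM2	33.0	21.3	32.7	13.1	46.1	-0.2102	0.4328	291
chrM3	24.3	25.7	32.1	17.9	42.2	-0.1111	0.1525	140
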