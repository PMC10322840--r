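sequence	landmark	position	residue	note
BRAF_synth	G464	464	G	P-loop
BRAF_synth	G466	466	G	P-loop
BRAF_synth	F468	468	F	P-loop
BRAF_synth	G469	469	G	P-loop
BRAF_synth	K483	483	K	VAIK lysine
BRAF_synth	L485	485	L	beta3
BRAF_synth	V487	487	V	beta3-alphaC
BRAF_synth	Q494	494	Q	QLQA span
BRAF_synth	L495	495	L	QLQA span
BRAF_synth	Q496	496	Q	QLQA span
BRAF_synth	A497	497	A	QLQA span
BRAF_synth	F498	498	F	alphaC hydrophobic network
BRAF_synth	K499	499	K	alphaC
BRAF_synth	L505	505	L	R-spine
BRAF_synth	R506	506	R	RKTR/DIF
BRAF_synth	K507	507	K	RKTR
BRAF_synth	T508	508	T	RKTR
BRAF_synth	R509	509	R	RKTR dimerization arginine
BRAF_synth	D576	576	D	HRD catalytic aspartate
BRAF_synth	D587	587	D	beta7-beta8
BRAF_synth	L588	588	L	beta7-beta8
BRAF_synth	D594	594	D	DFG
BRAF_synth	L597	597	L	activation segment
BRAF_synth	T599	599	T	activation segment
BRAF_synth	V600	600	V	activation segment
BRAF_synth	S446	446	S	NtA SSDD
BRAF_synth	S447	447	S	NtA SSDD
BRAF_synth	D448	448	D	NtA SSDD
BRAF_synth	D449	449	D	NtA SSDD
Pl_KSR3_synth	C37	37	C	C1/CRD
Pl_KSR3_synth	C40	40	C	C1/CRD
Pl_KSR3_synth	S84	84	S	N-terminal 14-3-3 pair
Pl_KSR3_synth	S87	87	S	N-terminal 14-3-3 pair
Pl_KSR3_synth	S306	306	S	NtA
Pl_KSR3_synth	E307	307	E	NtA
Pl_KSR3_synth	R343	343	R	beta3, homolog of B-RAF L485
Pl_KSR3_synth	VTA_insertion_point	345	P	site of the 3-residue beta3-alphaC restoration insertion
Pl_KSR3_synth	L354	354	L	alphaC, homolog of B-RAF K499
Pl_KSR3_synth	S361	361	S	SKIR dimer motif, homolog of B-RAF R506
Pl_KSR3_synth	K362	362	K	SKIR
Pl_KSR3_synth	I363	363	I	SKIR
Pl_KSR3_synth	R364	364	R	dimerization arginine, homolog of B-RAF R509
Pl_KSR3_synth	K443	443	K	beta7-beta8, homolog of B-RAF D587
Pl_KSR3_synth	V444	444	V	beta7-beta8, homolog of B-RAF L588
Pl_KSR3_synth	D452	452	D	acidic activation segment
Pl_KSR3_synth	D455	455	D	acidic activation segment
Pl_KSR3_synth	S586	586	S	C-terminal 14-3-3 serine (HSLSEP)
Pl_KSR1_synth	R608	608	R	dimerization arginine
Sk_KSR3_synth	D293	293	D	NtA
Sk_KSR3_synth	E294	294	E	NtA
Sk_KSR3_synth	R350	350	R	dimerization arginine
Sk_KSR3_synth	S572	572	S	C-terminal 14-3-3 serine (HSQSEP)
Nv_KSR3_synth	R390	390	R	dimerization arginine
Nv_KSR3_synth	S618	618	S	C-terminal 14-3-3 serine (GSHSEP)
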