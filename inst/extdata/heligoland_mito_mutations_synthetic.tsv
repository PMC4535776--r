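# Reconstruction of the published table of new mitochondrial genome mutations
# (control region excluded) in the Heligoland house mouse cohort.
# Positions are 1-based coordinates on the mouse reference (NCBI37/mm9) chrM.
# Per-animal cells: "." = consensus base; "X/Y" = heteroplasmic double peak.
# The six comparator-species rows are transposed into columns. The published
# table is only available as flattened text whose row-to-column mapping is
# ambiguous; this file encodes a reconstruction that is internally consistent
# (one fixed carrier per position, heteroplasmies co-occurring with a fixed
# carrier elsewhere in the cohort) and reproduces the published summary
# counts (10 counted positions; 3 fully conserved across the six species).
position	annotation	consensus	HG_01	HG_02	HG_05	HG_06	HG_08	HG_10	HG_11	HG_12	HG_13	HG_14	HG_1450_2	Rat	Human	Orangutan	Dog	Horse	Opossum
1080	tRNA-Val	A	T	.	.	.	.	.	.	.	.	.	.	A	A	A	T	A	T
4771	ND2	C	.	.	.	.	.	.	.	.	.	.	T	C	C	C	T	A	A
5157	tRNA-Asn	C	.	.	.	.	.	.	.	.	.	.	T	C	C	C	C	C	C
5163	rep_ori	C	.	.	.	.	G	.	.	.	.	.	.	C	C	C	C	C	C
10688	ND4	T	.	.	C	.	.	.	.	.	.	.	.	C	A	T	A	A	A
10689	ND4	A	.	.	.	.	.	.	.	C	.	.	.	A	A	A	A	A	C
12009	ND5	T	.	A	.	.	.	.	A/G	.	.	.	.	C	A	C	G	G	A
13681	ND6	C	.	.	.	.	.	.	.	.	C/T	T	.	A	C	C	G	A	C
14698	CYTB	T	.	.	.	.	.	.	.	.	.	C	.	C	T	T	T	T	T
15163	CYTB	G	.	.	.	A	.	.	.	.	.	.	.	G	G	G	G	G	G
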