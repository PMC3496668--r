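codon	aa	preferred
TAA	*	FALSE
TAG	*	FALSE
TGA	*	FALSE
GCA	A	FALSE
GCC	A	TRUE
GCG	A	FALSE
GCT	A	FALSE
TGC	C	TRUE
TGT	C	FALSE
GAC	D	TRUE
GAT	D	FALSE
GAA	E	FALSE
GAG	E	TRUE
TTC	F	TRUE
TTT	F	FALSE
GGA	G	FALSE
GGC	G	TRUE
GGG	G	FALSE
GGT	G	FALSE
CAC	H	TRUE
CAT	H	FALSE
ATA	I	FALSE
ATC	I	TRUE
ATT	I	FALSE
AAA	K	FALSE
AAG	K	TRUE
CTA	L	FALSE
CTC	L	FALSE
CTG	L	TRUE
CTT	L	FALSE
TTA	L	FALSE
TTG	L	FALSE
ATG	M	TRUE
AAC	N	TRUE
AAT	N	FALSE
CCA	P	FALSE
CCC	P	TRUE
CCG	P	FALSE
CCT	P	FALSE
CAA	Q	FALSE
CAG	Q	TRUE
AGA	R	FALSE
AGG	R	FALSE
CGA	R	FALSE
CGC	R	TRUE
CGG	R	FALSE
CGT	R	FALSE
AGC	S	FALSE
AGT	S	FALSE
TCA	S	FALSE
TCC	S	TRUE
TCG	S	FALSE
TCT	S	FALSE
ACA	T	FALSE
ACC	T	TRUE
ACG	T	FALSE
ACT	T	FALSE
GTA	V	FALSE
GTC	V	FALSE
GTG	V	TRUE
GTT	V	FALSE
TGG	W	TRUE
TAC	Y	TRUE
TAT	Y	FALSE
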