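aa	codon	freq
*	TAA	0.1981
*	TAG	0.5849
*	TGA	0.217
A	GCA	0.1167
A	GCC	0.4
A	GCG	0.35
A	GCT	0.1333
C	TGC	0.7634
C	TGT	0.2366
D	GAC	0.7634
D	GAT	0.2366
E	GAA	0.253
E	GAG	0.747
F	TTC	0.7634
F	TTT	0.2366
G	GGA	0.1167
G	GGC	0.4
G	GGG	0.35
G	GGT	0.1333
H	CAC	0.7634
H	CAT	0.2366
I	ATA	0.181
I	ATC	0.6207
I	ATT	0.1983
K	AAA	0.253
K	AAG	0.747
L	CTA	0.0775
L	CTC	0.2657
L	CTG	0.2325
L	CTT	0.0886
L	TTA	0.0923
L	TTG	0.2434
M	ATG	1
N	AAC	0.7634
N	AAT	0.2366
P	CCA	0.1167
P	CCC	0.4
P	CCG	0.35
P	CCT	0.1333
Q	CAA	0.253
Q	CAG	0.747
R	AGA	0.0775
R	AGG	0.2288
R	CGA	0.0849
R	CGC	0.2731
R	CGG	0.2399
R	CGT	0.0958
S	AGC	0.2527
S	AGT	0.0783
S	TCA	0.0819
S	TCC	0.2633
S	TCG	0.2313
S	TCT	0.0925
T	ACA	0.1167
T	ACC	0.4
T	ACG	0.35
T	ACT	0.1333
V	GTA	0.1167
V	GTC	0.4
V	GTG	0.35
V	GTT	0.1333
W	TGG	1
Y	TAC	0.7634
Y	TAT	0.2366
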