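# Default PPR-code scoring table: (5th, last) residue pair -> score per
# aligned nucleotide. These values are a simplified, package-supplied
# encoding of the qualitative preferences of the canonical PPR code
# (favoured ~ +1, neutral 0, disfavoured -1); they are NOT an empirical
# table. For quantitative work load a published table (e.g. one of the
# tables distributed with PPRmatcher) through read_scoring_table(); pairs
# absent from the table score the configurable default (0).
fifth	last	A	C	G	U
T	N	1	-1	0	-1
T	D	-1	-1	1	-1
N	D	-1	0	-1	1
N	N	-1	0.5	-1	0.5
N	S	-1	1	-1	0.25
S	N	1	-1	0	-1
S	D	-1	0	-1	1
T	S	0.5	0.25	-0.5	0
P	D	-1	0	-1	0.5
N	T	-0.5	0.5	-0.5	0.25
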