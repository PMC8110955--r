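# Default PPR code table: (motif type, target nucleotide) -> (5th, last)
# residue pair. These entries encode the canonical two-amino-acid PPR code
# (TN -> A, NS -> C, TD -> G, ND -> U) applied uniformly to all six
# contacting motif types. Edit or replace with empirically derived tables
# as needed; design requests for (type, base) keys absent from the table
# fail loudly rather than defaulting.
motif_type	nucleotide	fifth	last
P1	A	T	N
P1	C	N	S
P1	G	T	D
P1	U	N	D
L1	A	T	N
L1	C	N	S
L1	G	T	D
L1	U	N	D
S1	A	T	N
S1	C	N	S
S1	G	T	D
S1	U	N	D
P2	A	T	N
P2	C	N	S
P2	G	T	D
P2	U	N	D
L2	A	T	N
L2	C	N	S
L2	G	T	D
L2	U	N	D
S2	A	T	N
S2	C	N	S
S2	G	T	D
S2	U	N	D
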