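scheme	class	n_families
MEROPS	M	59
MEROPS	S	32
MEROPS	C	29
MEROPS	A	9
MEROPS	N	5
MEROPS	T	4
MEROPS	U	4
MEROPS	G	1
MEROPS	P	1
CAZY	GH	89
CAZY	CBM	31
CAZY	PL	17
CAZY	CE	10
CAZY	GT	7
CAZY	AA	2
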