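antibody	scale	octave	key	tick_size	bin_size
H3K27me3	minor	4	B	600	400
H3K27ac	minor	3	B	900	600
H3K9ac	minor	3	B	1200	800
H3K36me3	minor	4	B	300	200
H3K4me1	minor	3	B	1200	800
H3K4me2	minor	3	B	300	200
H3K4me3	minor	3	B	300	200
H3K9me3	minor	4	B	300	200
Pol2	minor	4	B	600	400
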