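wild_res	real_position	mut_res
R	273	H
G	245	S
R	249	S
R	248	A
C	242	S
H	168	R
V	143	A
I	195	T
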