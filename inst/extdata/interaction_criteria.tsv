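kind	type_a	type_b	d_min	d_max
aromatic_stacking	aromatic	aromatic	1.5	3.5
disulfide_bridge	cysteine	cysteine	1.4	2.3
hydrogen_bond	acceptor	donor	2.0	3.0
hydrophobic	hydrophobic	hydrophobic	2.0	3.8
repulsive	positive	positive	2.0	6.0
repulsive	negative	negative	2.0	6.0
salt_bridge	positive	negative	2.0	6.0
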