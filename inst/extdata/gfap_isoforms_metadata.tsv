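accession	species	isoform	head_rod_length
P03995.4	mouse	alpha	374
NP_001124492.1	mouse	delta_epsilon	374
synthetic_mouse_kappa	mouse	kappa	374
NP_002046.1	human	alpha	377
NP_001124491.1	human	delta_epsilon	377
ABL14186.1	human	kappa	377
AAD01873.1	rat	alpha	375
AAD01874.2	rat	delta_epsilon	375
ABL14185.1	rat	kappa	375
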