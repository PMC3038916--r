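species	coverage	type	raw	poly
armadillo	2.0	basecall	3.06	1.48
tenrec	1.9	basecall	3.19	1.08
hedgehog	1.9	basecall	25.10	23.71
cat	1.9	basecall	3.72	2.53
elephant	1.9	basecall	2.61	0.91
mouse_lemur	1.9	basecall	3.00	1.92
microbat	1.8	basecall	15.04	11.61
rabbit	2.0	basecall	5.63	4.08
bushbaby	1.9	basecall	4.94	2.59
rock_hyrax	2.2	basecall	3.72	2.68
megabat	2.6	basecall	3.73	3.01
shrew	1.9	basecall	8.04	6.62
squirrel	1.9	basecall	5.64	3.16
tree_shrew	1.9	basecall	4.43	2.01
squirrel	1.9	deletion	0.63	0.08
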