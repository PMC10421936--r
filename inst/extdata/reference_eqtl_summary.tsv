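condition	feature_type	relationship	n_pairs	n_unique
COPD	gene	cis	8195	938
COPD	gene	trans	110424	6629
COPD	mirna	cis	53	17
COPD	mirna	trans	557	221
ILD	gene	cis	10941	1142
ILD	gene	trans	68050	4249
ILD	mirna	cis	52	14
ILD	mirna	trans	362	144
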