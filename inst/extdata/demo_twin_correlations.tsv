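sex	trait	r_mz	r_dz	n_mz	n_dz
M	fpg	0.63	0.42	218	141
M	pg2h	0.57	0.45	218	141
M	log_homa	0.58	0.18	218	141
F	fpg	0.71	0.50	201	81
F	pg2h	0.47	0.30	201	81
F	log_homa	0.55	0.31	201	81
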