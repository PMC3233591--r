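sex	trait	conc_mz	conc_dz	prevalence	n_mz	n_dz
M	ifg	0.667	0.439	0.282	218	141
M	igt	0.438	0.400	0.075	218	141
F	ifg	0.602	0.385	0.189	201	81
F	igt	0.231	0.000	0.065	201	81
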