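chrX	0	2e+06	1
chrX	2e+06	4e+06	2
chrX	4e+06	6e+06	3
chrX	6e+06	8e+06	4
chrX	8e+06	1e+07	5
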