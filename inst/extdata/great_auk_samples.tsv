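sample	accession	coverage	relaxed_length	strict_length	library_type
MK131	MF188883	74.40	16001	15067	single_stranded
MK132	NA	6.23	13267	3312	single_stranded
MK133	MF188884	23.04	16251	14240	single_stranded
MK134	MF188885	288.62	16607	16526	single_stranded
MK135	MF188886	88.90	16554	16356	single_stranded
MK136	MF188887	67.83	16330	15833	single_stranded
MK138	MF188888	9.76	16509	7866	single_stranded
LastGA2_Heart	MF188889	430.09	16698	16649	double_stranded
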