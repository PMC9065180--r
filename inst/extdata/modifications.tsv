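name	targets	gain	loss	delta_da
carbamidomethyl	C	C2H3NO		57.0215
oxidation	M	O		15.9949
deamidation	N	O	HN	0.9840
Nterm_formylation	N-term	CO		27,9949
Nterm_acetylation	N-term	C2H2O		42.0106
Gln_to_pyroGlu	Q:N-term		H3N	-17.0265
Cys_ammonia_loss	C:N-term		H3N	-17.0265
Lys_to_aminoadipic_semialdehyde	K	O	H3N	-1.0316
Arg_to_glutamic_semialdehyde	R	O	CH5N3	-43.0534
Pro_to_pyroglutamic_acid	P	O	H2	13.9793
Trp_to_hydroxykynurenine	W	O2	C	19,9898
Trp_to_kynurenine	W	O	C	3.9949
Trp_to_N_formylkynurenine	W	O2		31.9898
Thr_to_2_amino_3_ketobutyric_acid	T		H2	-2.0156
Lys_methylation	K	CH2		14.0156
hydroxylation	F,P,H,W	O		15.9949
carbonylation	F,P,H,W	O	H2	13.9793
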