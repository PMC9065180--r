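exon_id	category	mode	sequence	partial_allowed
e1	constitutive	nt	ATGCATATTCTGTATAATCTGTATAATCTGCTGGGTTATGCTTATCTGGCTTTTACTAAA	TRUE
e2	constitutive	nt	TCTAATTTTACTTTTGAATCTGGTATTGAACCTTATCTGTGTATGACTCGTAATCATACT	TRUE
e3	constitutive	nt	TTTTATGCTTTTACTAATCATCTGCTGACTCAACGTATTGTTGCTATTTATAATTCTCCTAATGTTCCTCTG	TRUE
e4	constitutive	nt	GATCTGATTGCTATTCATGCTTATGCTTGGGCTGATTCTTTTAATTTTGGTCATATGGTTTTTTTTGCTTGT	TRUE
e5	constitutive	nt	GGTTATTCTCTGGATTGTCCTCTGCATCTGTGTCCTTATCGTTCTGATTATCTGTGTTTTTATCTGCAAGGTCTGTTT	TRUE
v2	variable	nt	GAAGTTTATTCTCTGCTGTCTAATTATTATTCTGGTCATTGTCGTACTCCTACTACTTTT	TRUE
v3	variable	nt	CAACCTTCTTATTATCTGTATATTACTCAAGGTTCTCATTCTCAT	TRUE
v4	variable	nt	ACTCCTTCTAAACAATATCAACTGTCTTCTTCTCATTGTATTCATCTGCGT	TRUE
v5	variable	nt	GTTTCTTCTATGAATTATTCTGTTCTGAAAACTAATCTGCTGAAACCTTATCCTTTTACT	TRUE
v6	variable	nt	TCTACTACTCATTGTTCTCATGTTTATCTGCCTCTGTGTTATTGGGAA	TRUE
v7	variable	nt	CTGTATTATCTGACTCAATCTACTATTTCTTCTCATTATAAAGTTGAATATTCTCGTCAT	TRUE
v8	variable	nt	TGTTGTGAACAACTGGATCTGTTTTCTGTTGGTTCTTCTGGTGATTCTGCT	TRUE
v9	variable	nt	TGTATTTTTACTCTGCCTTCTACTTTTTTTTCTTCTTCTTCTCCT	TRUE
v10	variable	nt	CATGGTTTTCTGGCTCCTTTTAAACAATCTCTGCTGCTGTCTTAT	TRUE
e15	constitutive	nt	TTTCCTTATGGTCCTTTTCCTCGTCTGTCTGATCATCTGCAAGAATTTCTGTTTACTGCTCGTGATATT	TRUE
e16	constitutive	nt	TCTCGTCATCAAAAAACTATTTTTCATTATCTGTCTTATCAAAATACTGATCAATTTACTTCTACTCATTCT	TRUE
e17	constitutive	nt	CTGAAATGTTATCAAAATACTACTGCTGCTTTTCAACCTACTCTGTTTCTGATTCAATGTCTGATTACT	TRUE
e18	constitutive	nt	TCTGCTTTTCTGCTGCTGGTTCTGGGTCTGCGTTCTTGTTCTTATCTGGATCTGTATTTT	TRUE
e19	constitutive	nt	GAACATGGTAATTCTTATGGTACTAATCTGTGGCTGTGTCAACAAGCTTATTAA	TRUE
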