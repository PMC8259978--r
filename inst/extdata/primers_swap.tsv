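construct	context	element	donor	mode	forward	reverse
Rh3-RCSIIswap-Rh4	Rh3	RCSII	Rh4	insert	acaatgctaatccaattcggttgcgatgggccgtataaaa	ttttatacggcccatcgcaaccgaattggattagcattgt
Rh3-RCSI+IIswap-Rh4	Rh3	RCSI+II	Rh4	swap	tcccgctgcgacaatgctaattgaatttggttgcgatgggccgtataaaa	ttttatacggcccatcgcaaccaaattcaattagcattgtcgcagcggga
Rh3-RCSIswap-Rh5	Rh3	RCSI	Rh5	swap	taatcccgctgcgacaatgctaattagattccgatgggccgtataaaagc	gcttttatacggcccatcggaatctaattagcattgtcgcagcgggatta
Rh3-RCSIswap-Rh6	Rh3	RCSI	Rh6	swap	taatcccgctgcgacaatgctaattggattacgatgggccgtataaaagc	gcttttatacggcccatcgtaatccaattagcattgtcgcagcgggatta
Rh4-RCSIswap-Rh3	Rh4	RCSI	Rh3	swap	aaccacaaagtctaatccaattcggttggcagcacaaaatgcgat	atcgcattttgtgctgccaaccgaattggattagactttgtggtt
Rh4-RCSIswap-Rh6	Rh4	RCSI	Rh6	swap	aaccacaaagtctaattggattaggttggcagcacaaaatgcgat	atcgcattttgtgctgccaacctaatccaattagactttgtggtt
Rh5-RCSIswap-Rh3	Rh5	RCSI	Rh3	swap	ggtcaccacttaatccgtcttaatccaattctttggcgggctataaaagc	gcttttatagcccgccaaagaattggattaagacggattaagtggtgacc
Rh5-RCSIswap-Rh6	Rh5	RCSI	Rh6	swap	tcaccacttaatccgtcttaattggattatttggcgggctataaaagca	tgcttttatagcccgccaaataatccaattaagacggattaagtggtga
Rh6-RCSIswap-Rh3	Rh6	RCSI	Rh3	swap	ggccaagtgccggctaatccaattcgggcaattagtcta	tagactaattgcccgaattggattagccggcacttggcc
Rh6-RCSIswap-Rh5	Rh6	RCSI	Rh5	swap	ggccaagtgccggctaattagattcgggcaattagtcta	tagactaattgcccgaatctaattagccggcacttggcc
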