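rh	forward	reverse
Rh1	agatctataatccaagattagcagag	gcggccgcattctgaatatttcactggg
Rh3	agatctgcactaaccttcagatgagc	gcggccgcgtctgcgggccaagacgaaatca
Rh4	agatctgtttctttggacaatgttg	gcggccgctcggtcaacccgataccgaa
Rh5	agatctaacatgtaaagcttgtaaaa	gcggccgctagtttcctttgcaggtcgac
Rh6	agatctgggtgggtggtacctcaaac	gcggccgcggtggcgcttcggtggtggcttc
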