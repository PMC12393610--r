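>synthetic_minicircle_601bp seed=601 circular=true
TTATGGGGGTCCCTCTGCTCGCTAGGGATCTGTTTTGACCTTCGTACTTGTACGGGCCTACCTAGGCACT
ACATAAGCAAAGTCCCAGTCCGCCGTCATCCCTGCCTGCCTATGGAGGAGATTAGGGCATCGAGAACGGC
TCCGATGGTTACCATAGTTGGGGGGTTGAATCAAATATACACAAAATGCCAATAGGAGTCAGAACGTTAT
AGTCACGGAGCGGGTACTTGGAGGGATAGTACAAAGGTACCTGCCGGGCAAACGAAACGTAATCTGTTCG
GATGTGTCAAAGGGGAAAGAAAGCGGGACTTTACTTGCTTCAAGGCATATGGCACACGCCGGTTAGCATG
CGAATGCTTTGCGAAATCGGTATTATTTGCCTGAATGTATCGTTCACCATAATTGTAGTAATTTTCTTGA
AGTCGTTGTTGGCATATACAAAATAGAGAACTCGTTTGCACGCTCCAGAATGCTCCTCTGTGATTCAATT
CCGTAATAGGAATGACTGTAACCGCCTTATTCGCACCGTTTTAAGTCTGCGTCTCTTTGTCGAGTGCGTA
CAATTCAACAGCCTGAATGTAGTGTTAACCCTCGTCGTCTT
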