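>wt Cox15 N-terminal IDR (amino acids 1-45), wild type
ATGCTTTTCAGAAACATAGAAGTGGGCAGGCAGGCAGCTAAGCTATTAACGAGAACCTCG
AGTCGTTTGGCCTGGCAAAGTATTGGGGCCTCAAGGAATATTTCTACCATCAGACAACAA
ATCAGAAAGACTCAA
>low_pI Cox15 IDR variant, every R mutated to E
ATGCTTTTCGAAAACATAGAAGTGGGCGAACAGGCAGCTAAGCTATTAACGGAAACCTCG
AGTGAATTGGCCTGGCAAAGTATTGGGGCCTCAGAAAATATTTCTACCATCGAACAACAA
ATCGAAAAGACTCAA
>low_hydrophobicity Cox15 IDR variant, L to N, V to K, I to R
ATGAATTTCAGAAACAGAGAAAAGGGCAGGCAGGCAGCTAAGAATAATACGAGAACCTCG
AGTCGTAATGCCTGGCAAAGTAGAGGGGCCTCAAGGAATAGATCTACCAGAAGACAACAA
AGAAGAAAGACTCAA
>sim synthetic Cox15 IDR evolved in silico without feature constraints
ATGCTGCTGAGAAACGTTGAATCCTCCAAACCCGAAGCAAAACTAATTACCAGAGCTTCT
TACGCCGTGCCCAGGAAAATGAACAATTCATACTTGGGCGATAATACATTGAATAACCTG
GTCTTAAAGAAGAGCTATCTTTTAGCTGTTCCCAGAAAGATTCCCACGATTCCAGCCAGT
CTGCCGCAAATTCGTGACAAGGAT
>sim_high_pI synthetic IDR with E and D mutated to R
ATGCTGCTGAGAAACGTTAGATCCTCCAAACCCAGAGCAAAACTAATTACCAGAGCTTCT
TACGCCGTGCCCAGGAAAATGAACAATTCATACTTGGGCAGAAATACATTGAATAACCTG
GTCTTAAAGAAGAGCTATCTTTTAGCTGTTCCCAGAAAGATTCCCACGATTCCAGCCAGT
CTGCCGCAAATTCGTAGAAAGAGA
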