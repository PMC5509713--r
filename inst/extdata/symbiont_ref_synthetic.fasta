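>symbiont_ref_synthetic_1
CGCATAAGGCTTGGTGCCGGTTACTCCGGGAGGATCCTAGGTGATGGAACGGGGCTCTTCGTTTGTTGGA
TTTCTACCAAGCGCAGCACCGGTCCTAATTATGAGTGTCAATATATACGTGGCCATGGCTGACAGCACAA
CGTACTACTTCTATGGTAATTTGCCCATCGAACTGACCAGACCCGCCATTATCCTACCCACCGCTCGGTC
CGGCAGACTTTTACACTAGTAGAAATTGGACATTTTTATAATAATCAAGCAGGTACTGGATGTCCTATTA
CTTACCAGGCTGATTTGTAGCCGGAATGGCGTAGAATGCCTCCTCGACTGTCATTTACCTTCGGGAAGCT
GCCCCCTGTCTCTCATAACAACTCCTTAATGTGTTTCAGGGAACCTGAGACTACGAACCGCGGTAGCATC
TTGTTTTCTTAGACCTATCGAACGAATGGAATCCGTATACGCATACCTTTAAAAGACTTAACGTAGCGAG
TATGTCTGATGACTTATCGGTTGTGATAGATGTTCTAACAGGCTTTCGACAACGACCTGAGTCAGCCGTA
TTGGCTCAATGTTAGCTAGCGCCTACGTGTCGCATTTACGATGTTCCCGCATCATGCACTAAGTTGTCCT
CATAATTCCAGCCCTGTCGACAGCGGGTAATCGAACCGTATCGCTGCTTC
>symbiont_ref_synthetic_2
TTTCTTGGCAGTTCCAGAGGTTTAGGGTTCAACGCTCGGGTAGCAAATGTCCAATCAAAGACGGTGTGTC
CGCAAGAGTAGATACGACGCTTAGGAGTTTTCCTGATGCATCCACGTGCCGGGCGCTAACCTGATGGGAC
CGCCGATTTCCTGCATTTCCAGAGTCTGTACGCATATCTTTATCGGATAACTGGCTATTGTATTATGTAC
CCTATGGACAAAATAATTAATGTACATAGTAGTACTTTGGCACAGCACAAAAGTTCGACTAAAATCGCCC
TTCTAGTAAAACCTGCCAAGTTGCAGGCGGACTAGCTTCACTAAGGGGTAAAAAACAATGCTGGATCTCG
AAATAAGTCTATCTCTTGGATTACCTGTTAGCTAAGAAAGTATCCAAACAAATTTAAACTTCTACGTTTT
GCAAGGGTAAACGTCCACTTTCGATATGAAAAGACGACGTAATGCATACACTCCGGGACGGATAGCGCTC
TCCATCGCGATCATATATGGGTTTGTAGACGTACTAGGATCTTGTGACCAATGAAGCGCGTTCATCTGGT
GTGGAAAGGAATATTAGCGCAAGATTTGCATTTATTACGAGGCTCCGGGCTTATTAGAGTGCGCGGTTAG
AGTGATCTCATTGATATTAGCTTGATCCTTGCGCCAGTGCGGGTAGGTGTAGCGCATCCCTTTAGCAATC
AGCTTCGGCCGTCGTTGCAT
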