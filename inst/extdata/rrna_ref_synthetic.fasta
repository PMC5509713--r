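>rRNA_ref_synthetic_1
GCCAACTTGCGATCGAATGGAATCCGGGATACCCGCCTACATAGTTCTGCGGGGTCTTATGACCAGGCTC
CCCGATTGAACAGTATACCAACGCCCCAGGGGGGAAGTCCAGGATCTTAATTTAGACAAGGATACGTGGG
GTTTGCGAAGGGACGACGTAAGGTCGAGCCCCCTGAGGTGCTAAGCCGTATCCGTGGTAATAGAAGGATC
TCACCGTCAGTTAGCAGGGCCTTAGTAATCGGTATCCGAGCCAAGAGGTAAGGCTCGTAGTAGTACACGC
GCTATCGATAGGGTCCGATTACCGTGTACCATCGTGATGATTTGACGGCTGTCACGAGACTTAAGCTGTT
AATTTAAGCGTGGATACGTCAGGCTCCATCAGCCTTGGAGCAAACGGTTATTGATGGAATGGCTAGACTC
TTTGTTACATCTACCGGAACCGTTGCGCGTCTCCAATAGATTTATTCATTAAAGACCTCCACGTCATCGA
CGACATTTCGATTCCATGGGGCAAGTCACTGGGCGGGTAGCGTAATGGTGCTACCATTTGGCCGCGGCGC
TTAGTTTGCTCTGTTGCGTTTCAGGTGGCCGGCAATTAAATCGTGACATCCCTAGCGGCTTGTGTCAGCA
AACGTTTTCATGCGGCTGCATGCTTTAAAGGACGAGGAATAGTGGTAATAGGTTATTGTCTGACGTGAGG
TTTAAGATCAGAGCGTACAACTAGATGCACCCCGGTGAAAGTACGATAGAATGATGGGCCGGAGACACTA
GGAGACTGTATTCCGTGGGATGGGGTCCTT
>rRNA_ref_synthetic_2
TGGGCGTGCGGCCCCCATGAGCGAGTCGCCTGGCACTGCGGAGCTGGTTTCACGCAAACGCCTTCTAACA
CGCACTATGCGTAGGGCTTATGGTCACTGGCGAGTGCAATCCACAACTCGGTGTTACAACTTCAGTCTAC
TATCGTGCTAATCAGCATTCGTCATAGAACGCTGACCGAGCTGGTGGGAGGCTAATTAAAGCCTGTCTAC
ATGATAACAAACTCACCTCTTTCTATGTTGGAGTACTGCAATAACGCCGCTCGAACTGCGGGGGAGCTGC
GACATGACAAGTCGGTAATTGGGCGTCTCACGCGTAGGCGAGGAGAACTAAGAGACTAGTCGGCTGAGTA
CTTGGGTATACTTGGTTATAAAACACGGTGGCCGGGCGAGTTACCACTCACGTATATGCGCGGTGTTTCC
TATCTGACGGTGGGTGTCCTATCGTCATGTAGGAAGGCCCGACTATGCTCCATAAGGACTAACGTGTTAG
TCAGACATCGTTAAGCGCCTCGCTGACCGAATGTAATTGAACGTAATTGGGGTTTCCTCAAATATCCTTA
TTCCAATGACTCGGGATTCTCCATTCTTTGCCGTCAAACCTTGTCGCCCACAGGGAAGATTCTATTTGTG
AACGTCCATAAGCAGTCTAAGCGGAAGGTGAGTTAATATTAGTGCTGGTTGGCATTTTCAATCTCCTTCT
CTGACTACGGTCCCGAGACGTTGCCAGGAGCAAAATCCCATGTCCGCTGGATCTGCGACCTCCAATTAGG
TATGAAGTGGTCGGAAAGTTGTTCGTCTGACCGGGAACCAGTTAATCCCCTAGGGTGACATGCTAAATCC
TAATCAGACA
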