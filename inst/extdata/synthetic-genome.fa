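>chr1
TTAACTTGAATTAGTAGTCCCGCGCATTACTACCAAATGAGATCCCTAGTAATACTGCACGGCGAATGGG
TCCAACACGTCCTACGCAATCTGGGCCCACCGCAAACGGTACCAGTATGTGTTTCTTAGCATCATTTAAT
TTTTTGCAGGCGTATGCGTAGGAGCTCTCAAGGCTTTCGAACAGAAAGCGATAGCTTCCCTAGTAGAGGA
ACCCTCTAAAAACTTATTAAGTGCCCGGCTTCCTCCCGCGATCCCCGTCTAATCGTTGGCGGCCCGCAGT
CGCAATGCGCCCACGGAGTATACGCATTCGATTCCCCCTGTTGGAACGCGTCGTACTCTGGAAGCCCGCG
TAGGAGGTGAACAAGAGTGGCTACCCAGAGAGAATGCGGCGTAGACACGTCTATCAGTTTCGACCGAAGC
ATATCAACATCCAACCAATCCAATCGTTGACAGATAGTAGGCAACGTCATCAGCCGGATCCGCTCTATCG
GTCCCTTTCAAGATGCAGTTTGTAACCGAGTGACGTCAGTAAGCGACGTTGCGGCATGACAGACTTAACA
TGACCTTCCATCAATGCAAAGGCAGCATCTAAATCAACAGTCGCTCGCGGGGGCTTATTCGAGCGCGGAC
CAGCTTGACGGCTGGAGTTTGATGCGATGCTTCGAGGTACATTTCCCCTATTGCGACGTATGCCGTAGCT
TCTCGTGAAGAGGTTAGAGACTAAGTCGGATAAATAAATCCGCACATATCCTGTTGGTGACAGTTTCTTC
CTGGTCTCCCCGCGATAATGTCTTTTGCCCTTAATCATGCCCTGCGTTCCTCACTTGGCCCTCTGTTCGC
ATGCTATTCCTCTGGCCTATTATCCTCTCATGGTTTCTCAGAGAGAAGGAGGGGATTATTCAGCGGTACG
TAAAGCGCTGGCGCAAGAATAATAGTGACATCCCCATCCGCTCGTTCGGTCGAGGCACTGCTTAGCGCCT
ATCAAATAAGCCCATGGCGAGAGCCGGAGCGGCTAAAGTTTAAGAATACTGTAGCAGGCCGTTCACTAGT
GGAAAAAGCCTGACCGCAACCCTGCTTGTGAGCCGTTCAGGCACTTTCTCTTTGTAATGTAGAATCCGTC
CCTCACAGAACCCATCCAAATAGTCCCATAGAACCCGGATTAAGAACCAAGTTTCCAAGGGCCGCACTTT
TATGAGCTTGCGATACTTCTTGTAGTAAATGAACGGTTCCAGAACTAGCTATCAGTACATGTTATTCCGA
AGGCTTGTGACGCGCAATGTTGTTCACCGAAAACACGGGACCATTCATGGCTTAACCTTTAAGTCGCATC
CCTCAAACCGATCTCTCAGCTATAAATTAATCAGTTCTGTACGGTCGGCTTTAATCATGCTGCCGGCCCC
ACGTCAACGTCGCATCGTCAGTAAAAGTACAGGCCATCAGACCTCATACTAGCCCTGAAACCTTGAATGG
CTATGAAGGACCTACAATCCTGTACAATCATGCATGGGAGGTGAAATAGTCCAGCGCTCGTCGGTCTCAT
CCAGCTAGTCCTACTTCAAGAAAGTCGCACACCTGGGTCGGCGTCTAAATCGACTTCGCGCGATACGGCT
GGTGTCCCGCGAGCGGTCAAATATTCTTTTTACACGACCGAAGGCAAGTGCCCAATATTGAGTCAACGCA
CAGAGTCTATAAGGAGCAAACTCCGCGCTACAACTTCCCCAGACATGAGGAGGGATTTACATCTTTCGGG
CATGTGTTTCGCTCCGTGACGTTTTAGGGGGAGACTTGTTAAAGAGTTTATGCAGGATCCTGCCGGACAG
GACATCCCCAGCCCGCATCAACCATGCACTTGAACGCTGTCTTGCAAGATGCAGGAGATTCGTGGAGTCA
TCCCGACAGAACAAGCCTGACCTGCGGACCCATAGCAGCTTGATTGCGGCTTGATTGTCGCCCTTCCAAG
CCGTTGATCTAAGGGGACCTTCCGTGGCGGCACTAAGACTGTAAATGATATAACTGGAGGGTGTAGTGCA
TGACTGGTGAGAGCGGTCTCCCGGTCTGACCAAGTCGCAAAGGCGATCGCAGTTTTTTTCAAAGTCTGGT
TGCACCGGTTGAAGCGCTATATAGGGGCAGTTATGCCAGCATTCCGGGAGGAGATGCCTGGTCACGCGCG
AGGCCACGCGAAAAACAATACGCAGTCTTGGCGTACAACTGCTGTGGTGCGTACGGGGAGTATCATTATC
CTTGAGGGCCGGTACCCGGATGGGGATGGCCCTACGATTCTATATTGTCGCGACAAGCCCAAGTGTCCAC
CGTATTACTAGATTAAGCTAGAAGGACACGTCGTCAACCATACCAAAGGCGTCATTCTCAGCGCTTCCAG
AAACACTTGGCATACCACATGTTCACAACGTGGTGTGGGCCGACTACACCAAATCCATAGCGACTTGGGT
GGACTGGTGCTCGTGATTGATGTGGATCTTAACGTTTAGCAACTTTCCCTGGTGTAGTCCGACCCTAGTC
AGATTTAATGCGCAACACACTGGGTCCAGCGATGAGAGGCGTTGCTCCAGCGGACATAACCAGTTCGCCG
ATTCTGACTGCCTCCGACCTCGGAGGGAGAACGTCTACCACTGTGCGTTCGCTCGCGGGGCATGATCCAA
ATATCCCCTGGTCACTTGATTTTACGCAAAGTTTCCATGCCTCTCCCTGTTCAAACATCCTAATCTTTTT
GGGCATATCGGTAAAGGATTTGTAGTTAGCCATTGCAGCACCATACAATCGAAGGCCAAATCTATGGGTA
ATTAGCTGGGACCACCGAAGCGGTCCTTCGCAAACTCGCAATATGTGACCACAGCGTGCTTTCGGCATTT
AGACTGCTCACGCTCATTCTTCACTTAATGTCTGCATAACCCCCGGGGGAGTGGGGCAGTTGATATAGCG
ACTTGAAACGAGTCCAAAGCCTTGTACGGGCCACGACTCCGGGTGATTAATCGTCTTTATTGCCTGAGGA
CCTCGCCTGACGCGGTGAAACGGAAGTTGGTGAGGGTGGTCTCACTTCAAGTTCAGATCTGACATGACTA
AGTCCATTGACGACGACCTTTGGTGCGTTCAACTCTGTATGACTGAGCTTGATTTTATAAAACGCTCTAA
CTTCTATACAGGGACCGCAATGACGTTTCCACGCACTCTCTGGAGAACTTTCGAAGCCCTACGACAGAGA
AAGAGTGGGTGGGCACAGGTCGCCTGATGATCCCCCATTGTTCTTCGAAGTAGCAGGGTCCGATCGCATC
CTATTGTAGAATAATATTATTTCAAGCTGTAGCAAAATTTCTGTGTGCTCATTATGTCATTAGTAATTCG
TCGCTTACCCTATTGACAGTTACTAGTGGACGCCTCACCTGAAAAGAAAATGTGACAAGTCCTCATCCCT
TGGAAGAGGGGAATCCGCGACGTGCGTCCATCACGTGTGGACCCCCCCGTACCAATACTTTGTGCGTCGG
GGGATGATTGCTACCGTTAAACCAATCACCAGTAGATCACTCTAGTCGATGGCTCGCGAAAGCGTGGACC
GAACGAGGCGCAAGTAAAAGAACCTCTCTGGAAAATAGTGGTAGGACATCGGCCGCGTCCCCATAGCAAA
ACTCACGCCGCATCTCCAAGTCTAGCTTGTGGAAATGACCTTAGCAATATAGTCATGTGAGTCGAGTGAA
GCAGTGAAGCGAACCTTGAATAGTCATGCATACTTGCCTTAGTGCACCAATGACGGAGTGTCCATCCTAT
TGTGCTACTGGGAGACTGTGTTGTTTGAGGCGCCAACAGAGTTCTTATTTTGTTCAGATTCTCAGGTCCT
AAGACAAGTATATGGGTTCGGATAATCTTTGTCGTTAACTTAAGCTATGCGTTCGCCTTCCAGTGACCCT
GAGGCCGCTGTGGGTCTACACGCGAGCTTTGAATCCAAATTGCTGACACGACGACGACCTTAGATCAGTC
GGCCGCCGCAAGGTTTATCGCCGACAAATTTATGTACTTTGGCCCCCGGTGGGCATCCGAGTAGTACCAA
AGCAATCGAGGGGTGTTGTAACCTCATCATAAACTTCGAGCCCCGTAGACATAGTCCTACTGACCCTTAC
CTATACACGCTAATCTTCGTAGCGCACGTTACCCAAAAAGGTTCACACTAGTCCTGGCGTGCAGGTACGC
ATTCTGACTGCCTCCGACCTCGGTCGAGGCGAGCAACAGGTGGGGGCAACGCCGTCGGGCCGGTGACCGT
CATATTAGAACTTCCGTGCTACGACGCCACATGGGACTCACACGTCGTGGATGGGCAGGCGGTTTGTGGG
GGGATTATCACAGGCAATACAGTAGGATGGTAGCGACTCGAGTCCCAAGCCACCAGTATCTTTGAGTATG
GTGTCTAGAAATCGGCCGTGGACTAGAGTT
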