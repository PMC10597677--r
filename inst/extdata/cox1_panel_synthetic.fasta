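>SYN_Rotaria_magnacalcarata_like_1 synthetic cox1-like barcode (658 bp)
AGGGTATCTACGTGAGTCTAACAATACGGATTATTTGACATCCTTTACATGTTAATCCTGCATCTCGTAA
AATTGAACTGGTCGCGATGGCAGCGTTTATTGATAACTTCATATCTTATAATCTAAGACAAAGCTCAGAT
AGGAAACCCTAATTTTAATCCTGTCCTTTGCTTGGAGGATACATTATAGGCATGCCCTAGTCTACTTTAT
GGCAACTATCACCGTCCTCATATGTTCTTCCGTTTCCCTCGAACGATATATCTCCTAGATCGGCTGATTT
GATAGCAGCTCTTACTCTGATTACAGCTCTAAGGTATAGAGGGACAATTAATTAATGTATATAGTTCATA
ATTCGTAATTACACTATCCTTTTTTATTACTTCAACTATCGTTTCTTCCTTTGTGTAGCAGGTTCATTAC
ACATATATATATATATGATAAGGGTGGTTACCTCTAATGTTTTAAAATTTTATTAAATAGCAGTATTTTT
GACACTAATTTATGGCTAGTTCCTAGTATCAGTGCCTGTATGTCCACTCAGCGTTCGGAGTGTTTACTCT
TAAAGAACATCAACAATAATTTACCGGAGATTTTCAATCGGCCGGCGACGAGTTTTTTTAGATTTCACTT
GCTGTATATATACTTCTGTCTCACATGA
>SYN_Rotaria_socialis_like_1 synthetic cox1-like barcode (658 bp)
CTGTTTTGCTTATACGATTTACAGTTTTTCGATCTGGAATTGTCAAATTTAATCTTCTGTTTTCACGTTG
GAGTAAAGATTATAAAATTTACTTGCTGCCGAATATGCTTACAGAAGACCCTCAAGGGAAGCTATTCTCA
GTGTTCAAATTACACAATAATAAAGCAGTCTACATATCGGTATGAATATAAATGTGCTCCATTTTTATGG
CGTTAGTTATAAGAATGCCAGTTTGTCTGGACTGACTTGCCGATAGTAGTTGATTGAAGAATATTATACT
GGTGTAAGCGCGGTTCGGCACTATCTTTCAAAAGGAGTAAATGTAATAACAAGTGGATGGTCAACGACAC
AGCACAACCCTTTTCTGCGCGTATAATTTAAGATATGCAAAATGTGCAGTCGATATACATCCATATATTC
TCATTAATTGCGTGATGGTGTACTTATTCAGTTTATAAATTTTCTAAAAATTATCTGGTTTTTTAGTATT
TTAAGATGAGAATGTATTCTGTTAAGATAGGATTATCACGCTACATAGATCGACTATACATACTTGTTTA
CTACTACAAGGCCCTTTGCGTTATAGACTTATCGTTGCGGTTTTGTTTCATATAGGTTTAACCACTTACA
ATTCTTTATGTAGTTATGAATCGCATAA
>SYN_Rotaria_rotatoria_like_1 synthetic cox1-like barcode (658 bp)
GGCATTAATTACGAATTTGAGACTACTTATTAAGGGGACGCAATATCAAGTATGTTACAATTACTTAGCA
GTAAGTGCTGTATTTTATAAAGAATTCATATTTCGCATAGGCATTATAAGACAATGAATATAACTGCATT
AGATCATCTGATAGAGTTCAATTGGGTTAGCGAGCAATTGAATTTACTATCATCTCTTCATGTTTTTCAA
GTCTGATAACCGATATTTTCTCCGATTGGACAAAGGTAATTAAGGCATTAGTAACAGTGAATCGTTCTTC
TACTACGTAGATCGCATTAAGATTTATACCAAGTATGGGTAGCTTTCCTAGTTAGAATTTTTATCTGTTC
TGCCCATTGTCATTTGCTAAACGCAACATTACTTAATTGTATAAAACCCGCGTTTATGTTCTTGCAGTGG
AAAACAAATACATAACAATTCTGGGCAGGCTTGGTTCTCATACAGTAAAAATTATAACTACATTTTTAAA
AACTATTATATTATTAAAATGATATTATGAGAGAGCAAAGTTTCTTTCGTATCGACTTTTTAGTCCGCAG
AATTTTCTTTTACGTCGGCAAAGAGTCGACTACCGAAGTAATCGCATTAGCCCTGATAAGGTTGACAAAT
ATTACAGATAAGTTTCTCATATGACTAT
>SYN_Adineta_steineri_like_1 synthetic cox1-like barcode (658 bp)
ATCGAATTATTAACTTCGATATTTCCAATAAAAAAGTACATCTCTTCTCCCGATTAGAGGTTGCGTTTGT
GTAGAGGAGCTTATTATAGTAGCAAAATAAATAGCCGTGGTGAAAGCTTATTTCCAAAAATCATTAATAA
GGGTAGCAGGTTTTCTCTTTACATTAGGTGAAAGATTGATCATATGTAGTCTGATAATTGACATGGCATT
TACGTTGAAAAGTAATATATATGGTTTGGACGTTAGTTTTAAGATCAGACGAACTTAATGTAATCATATG
CAAGAAAGAAATTTTTTAAGTCACTTTATCAAGGTACCCTGCGGTGGTATCTTAGTTTGACCTTATTTAT
GTAGCAAGTTTCGGCTTATCCGAATATGGCACAACTATAAGCTATGGTCGGAGTTGAAACTTGGCTGTTT
ACACTACTAATTCAATGTATTTTCGTCTGTCGGCTCAATGGCTTCAAATTGATTCTGATCCCTGACTGTC
TTCCTTACCCTTGCTTATTTTTTTTAATTTTGCTAATTAGATCAGCCGATCGTGTATTACCCGAACTTCA
AAAGTTGTGCCAACTGTAATTAAACTATTATACGAGTTCTAGATGGGTAAACAGATAAGTTTATAGACAT
TCCATGATGAACTCATAGGCTCTCAATC
>SYN_Adineta_vaga_like_1 synthetic cox1-like barcode (658 bp)
TACCATCACGTAATTGTCCCACATATAAAACGGGCCATTAAGGTAAATTATTTCGAGTGAACCGCAATCG
TGGGTCAGGGGTTTGAATATACAAGGTAAGGAAAATGCATCCTGCCTCTGCCATATGATGATAACTACTG
GTTTAATTCAATTCTATATCGGCTAGTGTGAATTAAAACGCTTGTTCAGTATTAGAAAGACTGTAATGTA
GACGTATAGTACCGCTTTTTATCTTCTTCTAAAGTTTTTACTTAATCTTTTGAGTTCCATAAATCAACAA
CACTATCTGTACGTCCTGTGGTTGTATGACAATCAGTACATCTATCTGCTGTTCTTCTGGCGTCTCAAAC
CTCATAAAACTAGGTAAATTGTTTACTTAGGATTTCCAACTTGTACTGCTGAAGAAACGCAAAACATAAA
AATATGTCAATATTGACTGGTTGTTTTCTCCGTGCGGAGGGTATTTGGGATGGAAATCTCTTTCTGAGAC
GTATACCAAGGTACGGAAATATTATAAGATATATGCGCTTTCTTTTTCAAAATACTGTTTTAAATAATAT
CAGACTTGGTAATAAGAGGCAGCCTTTCTTCAACATAATCATTATAACATATAACCGAGTGGATTATTTC
GACTATGGGAGCGCTATAATTTAACATC
>SYN_Philodina_citrina_like_1 synthetic cox1-like barcode (658 bp)
CCAAGCTTATGTGTTGTCGTAGTCGCACTTTAACTTGTTATTCCAAGAGTTTAGACTCGGCAATGAAGGT
TCTAGACTGGCTCCGAATTATATCAATTACTCAATCCAGTATTGACACTATTGCTTATTATTATTATTTG
ATATACTTCAGTGGGTAGTCAATCTCGTCAACCAATTTATTTTTAAGGAGGGACTCACTCTAAAATTATC
TTCAAGTACTTAGAAGCATATAATTCAGTTAATGGATTTTTAAGAGATAGCGCGGGCAACTTGTAGATAA
TTCAAGGCATAAGTGTTCTCTTTGAGGATACTCAATGAAGGGAGCTTCCACAGAACATTTGACGCATTTG
ACTATTAACAAAGAAAAGTATAGTTAGTATGTAAAAGTGACTGCCTTATGGTGTCAATGCTTTGCGGAAG
CTCTAATGTAACACAAAATTAAAAAGGGCGAAGTTTGGACGATTACAGGAAATGCAACATATTCTGAATA
TCTGGTATAGCGAACATACTTATGTTCAACGGATCTTAGCGGGTGTTTCATAACAAAAGGGGATATGGAA
TCTAAAGTAAAAGTACAGAATTCATATCAAGATTACTCTGAATATAGTACCAAGGATATAAAATTAATAG
GTGGGGTTAAGTAGTTAGTAATCTCATA
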