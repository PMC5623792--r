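>Candida_inconspicua_IG_11
CAAAAAACAAAACTTTCAACAACGGATCTCTTGGTTCTCGCATCGATGAAGAGCGCAGCG
AAATGCGATACCTAGTGTGAATTGCAGCCATCGTGAATCATCGAGTTCTTGAACGCACAT
TGCGCCCTCTGGTATTCCGGAGGGCATGCCTGTTTGAGCGTCGTTTCCTTCTTGCTTGCG
AGCAGAAATGGGGGGGCCCTGGCATTGGGGCCGCTCTGAAAAGAAACGTTGCGGGCGAAG
CGAACTATGAGTAGGACGCTTGGCCGCCGAACTTAATACATAAGCTCGACCTCAAATCAG
GTAGGAATACCCGCTGAACTTAAGCA
>Debaryomyces_hansenii_1
ACTTTTGCTTTGGTCTGGACTAGAAATAGTTTGGGCCAGAGGTTTACTGAACTAAACTTC
AATATTTATATTGAATTGTTATTTATTTAATTGTCAATTTGTTGATTAAATTCAAAAAAT
CTTCAAAACTTTCAACAACGGATCTCTTGGTTCTCGCATCGATGAAGAACGCAGCGAAAT
GCGATAAGTAATATGAATTGCAGATTTTCGTGAATCATCGAATCTTTGAACGCACATTGC
GCCCTCTGGTATTCCAGAGGGCATGCCTGTTTGAGCGTCATTTCTCTCTCAAACCTTCGG
GTTTGGTATTGAGTGATACTCTTAGTTGAACTAGGCGTTTGCTTGAAATGTATTGGCATG
AGTGGTACTGGATAGTGCTATATGACTTTCAATG
>Debaryomyces_hansenii_IG_01
GAACTTTTGCTTTGGTCTGGACTAGAAATAGTTTGGGCCAGAGGTTTACTGAACTAAACT
TCAATATTTATATTGAATTGTTATTTATTTAATTGTCAATTTGTTGATTAAATTCAAAAA
ATCTTCAAAACTTTCAACAACGGATCTCTTGGTTCTCGCATCGATGAAGAACGCAGCGAA
ATGCGATAAGTAATATGAATTGCAGATTTTCGTGAATCATCGAATCTTTGAACGCACATT
GCGCCCTCTGGTATTCCAGAGGGCATGCCTGTTTGAGCGTCATTTCTCTCTCAAACCTTC
GGGTTTGGTATTGAGTGATACTCTTAGTTGAACTAGGCGTTTGCTTGAAATGTATTGGCA
TGAGTGGTACTGGATAGTGCTATATGACTTTCAATGTATTAGGTTTATCCAACTCGTTGA
ATAGTTTAATGGTATATTTCTCG
>Debaryomyces_hansenii_IG_II
CTTTTGCTTTGGTCTGGACTAGAAATAGTTTGGGCCAGAGGTTTACTGAACTAAACTTCA
ATATTTATATTGAATTGTTATTTATTTAATTGTCAATTTGTTGATTAAATTCAAAAAATC
TTCAAAACTTTCAACAACGGATCTCTTGGTTCTCGCATCGATGAAGAACGCAGCGAAATG
CGATAAGTAATATGAATTGCAGATTTTCGTGAATCATCGAATCTTTGAACGCACATTGCG
CCCTCTGGTATTCCAGAGGGCATGCCTGTTTGAGCGTCATTTCTCTCTCAAACCTTCGGG
TTTGGTATTGAGTGATACTCTTAGTTGAACTAGGCGTTTGCTTGAAATGTATTGGCATGA
GTGGTACTGGATAGTGCTATATGACTTTCAATGTATTAGGTTTATCCAACTCGTTGAATA
GTTTAA
>Kazachstania_unispora_IG_16
GCCGAACCAGCGCTTAATTGCGCGGTTTGGTGGGTCTCTGTAGCTCAGTAGCACTATTAC
ACACTGTGGAGATTTTATAATTCTTTGCATGCTTCTTTGGGCAGCTTCGGCAGCCCAGAG
GTAACAAACACAAACAACTTTGTAATATTTTTAACCCAGTCAAAACCAGAATTCCAGAAA
GATTTATCTTTTTGTAATATTATAACAAATATTCAAAACTTTCAACAACGGATCTCTTGG
TTCTCGCATCGATGAAGAACGCAGCGAAATGCGATACGTAATGTGAATTGCAGAATTCCG
TGAATCATCGAATCTTTGAACGCACATTGCGCCCCTTG
>Kluyveromyces_marxianus_IG_1
TTCTCATCCTAAACACAATGGAGTTTTTTCTCTATGAACTACTTCCCTGGAGAGCTCGTC
TCTCCAGTGGACATAAACACAAACAATATTTTGTATTATGAAAAACTATTATACTATAAA
ATTTAATATTCAAAACTTTCAACAACGGATCTCTTGGTTCTCGCATCGATGAAGAACGCA
GCGAATTGCGATATGTATTGTGAATTGCAGATTTTCGTGAATCATCAAATCTTTGAACGC
ACATTGCGCCCTCTGGTATTCCAGGGGGCATGCCTGTTTGAGCGTCATTTCTCTCTCAAA
CCTTTGGGTTTGGTAGTGAGTGATACTCGTCTCGGGTTAACTTGAAAGTGGCTAGCCGTT
GCCATCTGCGTGAGCAGGGCTGCGTGTCAAGTCTATGGACT
>Zygotorulaspora_florentina_IG_12
CTGACACATACACACAGTGGAGATATATTCTTTCTTCTTCTTCTTCTTTGGGGGACGGCG
GTTTGCGCTGCTGCTCCCAGAATGAAAAAACACAAACAACTTTTGTATTATTACAGATGT
CAAAACACAAAACAAAATACCAAAACTTTCAACAACGGATCTCTTGGTTCTCGCATCGAT
GAAGAACGCAGCGAAATGCGATACGTAATGTGAATTGCAGAATTCCGTGAATCATCGAAT
CTTTGAACGCACATTGCGCCCCTTGGTATTCCAGGGGGCATGCCTGTTTGAGCGTCATTT
CCTTCTCAAACACTTGTGTTTGGTAGTGAGTGATACTCTGTAACATGGGAGTTAGCTTGA
AATTGAGAGCCCATGGGCTGCTCTGCTGAGGCGGAAGTCGTGCTAGGTAACACCAACTCG
ACGCAACGCATTCGGCTGGACGCAGCTCCGGCGAACAAACACATCAACGCTTGACCTCAA
ATCA
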