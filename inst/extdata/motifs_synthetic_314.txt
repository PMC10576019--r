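GTGAG
GTAAG
GTATG
GTAAGT
GTGAGT
TTTCAG
TACTAAC
CTAAC
CTGAC
TGCATG
GCATG
TCATC
TCATT
CCATC
TAGGGT
TAGGGA
GGGGG
CCCCC
TTTTT
GAAGAA
GAAGAG
TGAAGA
CTCTCT
TCTCTC
GGGTGG
GGTGGG
CATCCCA
ATCACCT
GAGAGA
ATGCCCT
TCGCC
TCGCGA
GCTGCTC
ACTATAG
CGGTAG
CGGCCCA
GGATG
GCAGA
TTTCTTC
GGATT
TGTGA
CAACC
GTCTC
GTCTAAA
CTCCA
TGTAACT
CGGAAG
GAATC
CACTCGG
CTTTCC
TATCT
GTGAAC
CCCTGC
CGCCC
AAGTA
AATTAG
ATATTCC
CGACGT
TAGCGTG
CTTCCTC
ATGATC
TTAGGA
GTGAAA
TGGTCCT
ACTTCTA
CGAGC
CTGGTTT
CGGCTTT
ATGGG
CCGTTT
GTGGAGA
TTCCT
TTGCAA
CTCTGT
CAAGCC
GAGTCTA
GCTTTGA
ACAGC
AATAAAT
GTGTGA
TACGT
AGTCGTC
GAAAGCA
TTGAATA
TAACGA
CAAGGAA
CTACGAC
CTTTCT
GCATC
GCTCA
TTCGG
AGTTGCA
TTATCT
AATTAGA
TTTACCA
ACGTG
CCGAG
ATTTG
ATCGAT
AGTACCA
GACCGG
ATTTT
TGCACCC
GATCTA
GCGGCAT
CGACGC
CCAAC
GCTCCTA
AGACTC
GATCACA
TAGCA
TCGAGC
TAGATT
GTCGTCG
CTTGT
AGTAATT
TGGCTGG
ACCATA
AACTT
AGGCAAT
ATTGGA
GTATCCG
TATCCCT
GACTA
TCTTCTA
TGCGTG
AGGCC
TGCGT
ACCGAG
AGAGACG
TCCCAG
CCCAAC
GTGAACC
GCGTATG
TGGCGGA
TTCTAGA
GTACTA
AGTAC
AATCAC
GCACC
CAGCAG
TAGGA
CTAGTA
CATTAG
ACCCGT
GGAAAG
GTAGT
CTGCTAG
TTTCT
GTAGTT
GGCTCC
ACAAG
GTGCA
ACCAC
CGCAGGG
CTCGACT
GAAGCTT
TCGAG
AGGAATG
AAATAT
GAACTA
GCTGCCC
TAAGA
CGCGA
TGGAG
CTGCGT
TACGCC
CACTCAA
TTAGTAC
GGATCT
CACGTCA
ATGGT
GGAACG
CGAGA
TCTGTG
TGGAAC
AACTG
TTTAAAA
ATCCA
AAAGA
ACAGAT
GTCTTA
CGAACGT
GCTCTC
AAAGTCG
CCATGT
AACAC
TGAAG
TATCCAT
TAGGGG
GCCCTGT
CGAAG
ATCTTA
ACTGGTT
CAGTAC
GAGATC
CGTTA
GACAT
TCATGTT
AAGCCT
TCAAGC
GAACA
CCTACC
CTGTA
AAGCACG
GGGGTC
ATAAG
AGGTAT
CAGGCC
ATTCA
AAAATTT
CACACC
ATCAC
ATCTAT
CTGGGAA
TTTAC
GACTT
TGCGGG
GTGAAAT
GGGCC
TTGAGAC
TCACGG
GGTATGC
GCGGA
CGAGTA
GCGCAG
GCGTCGC
CCCCGT
GTCGCGA
ATGAGGA
AACTGA
CCCCTGG
ATGGAT
GCGTT
GTATTGG
TAAAGAT
CCGCGAA
ATATGC
GGGGGT
CCTGC
ACAAGAT
AGCGAC
TGGTAC
GGTTA
TGTCAC
CCCCCA
CCACA
CGCGG
GACAGC
CAGAAA
CCCGGA
AATGGAA
ATAGT
TATTCGG
ATGGCGT
AAGAGAG
CCGGT
GTTACG
ACTTACT
TCCTGAG
TCCAA
TACGAA
GAGCG
CGGCG
CTTAACC
GGGTTT
TCCCCTG
GTGAACG
GGAGC
GAAATCT
GTGCC
ACAGTGA
GACTGT
AGGCCA
TCACATG
CAGGTG
GATGACG
CTACT
CGACA
AGTGAT
GTTCG
CGCGGTA
TAGCC
TGGGTCA
GGATCC
AGATC
GATACG
TACCC
TCAGAGC
CGACAAG
TGTGG
CCGCC
GGTTAAG
CATGCCG
TGGCC
CGTACA
GAATCG
TTCTCCC
CGAAACG
CTTAGCC
TTGATTT
GCGAA
ATACGAA
CTTAC
CTTCAT
TCAGCTG
CTAGACG
CTGGGTA
TATTTT
AACGA
AGGCAT
ATCCAA
ACGGCCC
GAGCGT
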