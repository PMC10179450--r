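LOCUS       SYNMT001            1628 bp    DNA     circular PLN 01-JAN-2024
DEFINITION  synthetic demonstration organelle genome (generated data, not a
            natural sequence).
FEATURES             Location/Qualifiers
     source          1..1628
     CDS             101..466
                     /gene="orfA"
                     /product="synthetic open reading frame A"
     CDS             complement(617..892)
                     /gene="orfB"
     CDS             join(1013..1213,1244..1498)
                     /gene="orfC"
                     /note="two-exon synthetic gene"
ORIGIN
        1 ggcacacgcg gctgcacccg gtacattaaa gccagcttga ggttcacccg atgcctgcac
       61 gaacgcttat tcccctgtac acatgactta ctatcctgta atgaatggga ccgcaacact
      121 agttctagaa gcgagttcaa caacccggcg cttagggttt gcacggcatt cattttggcc
      181 gagcgatggt ctctctgtaa gctcaaccga agcatttaca ggcttaaaaa gcgcaaatag
      241 caatacctcg tcttcaaggc tagattcaca ctgcagtgcc ttcacagatt accgagttgc
      301 tcatgcgccg ggcaagtccg aatgggtatc cgcaataagt attgccgggt ggatgcatgt
      361 atattcgcca tgcagcagcg cttatacaac aagagtagaa ccggcctgtc cagctagaga
      421 agcgtgtatg tctacgagta catatcgtgt ttacgcttgc cgctaaaatt ccatgtcagt
      481 aatactctac caatacgtgc cttttacagg aacactcctc taaatcctat agttacagtg
      541 ataaggcttc ccattttttg gtcgcggtag ttgccgggtg tgctatatct taggtgagcg
      601 acttaggggc ccagatttaa aataagtgga ggtaggcaag acggtagagt gccccctgcg
      661 agtgcgagtc gggtcctgat ctcagtgccc gcttattctt gcatacatta gagattatta
      721 ccgctgcatt aagcgagaag ggaaaagggc ttaagtaata tacctttaga tggggagaca
      781 aagcaaccaa tgttcttact ttaatagaaa cgttgaataa acactgagat cccaaaagcg
      841 gacgggatgt cgatcgtatt aaaacaccat gacaccgtct aggatggtgc atgttgaaga
      901 cacgcgattt agttatacat atactatacg ggagcaaagc taagccttgc ggcgcttaca
      961 tactctgcaa gactataaga tcacggtacg agtacgcgta gtaaaagatg atatgtcctg
     1021 gcccatgcgt atgaattacg ttatttctac aattattgta gtatctgatc agggcgtgaa
     1081 gatacttgag atggatatag tcgggaaaaa cacttccacg cgtttaaagg cattcggcag
     1141 atgctacgtg tcagtcttgc ctggagatga gttctgcctg ggttccttaa gacgggtaca
     1201 aaaaatcact cctagtgata gaaatgcaac cagacgtgtg agtaccgtca catattggac
     1261 ggcaagatcg atctccagga ttttgaagac tacagtcata cccttggaga ccttctattg
     1321 gaacgtaaag tccgaagaac ccattagggg ctcagcctgg gtgtcgtgta ttgaacctat
     1381 tactcttctt ccacaagaat ggtgttacaa aggacttatc aatgaggtac gtgaaagaat
     1441 actgcagtta ccctggtcga cgctgtaaca tttattcagg tctattttat gtggatagcc
     1501 taactcgatg agaatttgta gattaaaagg gtagcagttc tctagacatg caccggcaag
     1561 cccagtatag tcaggctttc ggtagtaaaa cctacaatta atcccctgtt tgatcgagta
     1621 ctccgcta
//
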