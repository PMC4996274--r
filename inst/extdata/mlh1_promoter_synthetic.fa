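>MLH1_promoter_synthetic coords=-938..-337 synthetic sequence with CpG sites at assay coordinates
AATGAAAATAGGTCATTACATCCCAAACACTATATACACTCCCGATTATGATCACGGGAC
CCAAGTCGGTAACTCATAGAGGCATAGGCTAAAAGTGCCCAGTTGCAAGCTATAAAACAT
TAAAAGACCCGCGGGCTAGACTGCAACCTGCACGGTACTTACCGATTCATCAACGAGGTC
CCCCTCCAATTGGTAATTACAAGCCTTCGACAGAAACGCTTCAGCGACTACGGGATACAT
AGTCCGCGCGTACGACGATCGCTATCCATCGGACGTCCAGCACGTAATAGCATTCGGACC
ACCGCAGGCCGACGCGGCCGCGAGTGTTGACGACTAATCGCCGGTTACTGCTAATTTCTC
TCTGCTCGGCCCTCGCTGCCCCTGCCTCTCCTAGTCGAACAGGAAATACGCAACGAAAAC
TTGTGTCTCCGGCGAAGGGCCAAGCTGGTTTTATATGCGCATTAGAACATCTGCGGAGAA
TTGCCCAGGCGGCTACTTTATTCTACAACCCGTGGGAGATAGTAAGTTTTCAAAGATTCG
AGCTCAATGACCACCGTTCAACGAACTCATCTCTAATCCATCCCAAATCAAAACGTTATC
GA
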