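>pde4b_region_synthetic (synthetic stand-in sequence, not hg19)
TCCATAAATAAACATGGTCCAAGATTGATAGGAAGAGTACTAGGTATTCATAGTGCTTCA
TGGAATCAAGTGATAATAAACTGCAGAAGCACTCATCTACGGCCTCTGTAATGACTTTAG
CCACGCACAGTCCACCGTTTTACATGACTCGGTAATTTTTTGGCTCCCAATTGAGGACGG
GACCGGGTCTTCTCGCTATCAACTCCACCCTCCCGATAGGCATACGAGAATTCCGGCTCT
TTCTATACGAACCTCGGTAGGCCTCTGCGAACCTGTGAGCAACCGGTTAAGGCTACCTTA
CCGATTTTCCTTGTTCTCAAGCAATCTCCCGAACAGCCTGCGTAGATTCTCCAGGCCAAG
GGGCTCGGTTGACTCAGTGAAACCTTCGACTGTAACTCTGAAACAACTCGCCTCGAACGA
CAGTCGAGCAGCTCTGCGGAGGCCTCTGGTCCCCATTTTGGTACGCTCGTCTTTGTGTCA
CGTCCCAGTCTACATCAGTACAGTCACATGGTCCTGGACGGTACAGCGCTCAAATCATGA
ACCCCGCATCGAAAAATTCTCGTGGCACCACGTTCCGTAACTAGTTCAGAGTAACGCGTG
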