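>A synthetic COI-COII spacer exemplar (non-empirical stand-in)
CGGCAATTTAAGGAGGCTTGCAAGTCCGTCATCATCACTCCTTTGTATCTAGGCGCAAAGTGGCACGCGCCCGTCGTGACTTAGTAATGGTCATGAAATGCCCTCGAATCTGCTGCCAAGGACCCTCGGTAAGATACTGATCGATTCCAAACCGCCTATAAGAATGACAACCCGGGGCGGCATATCTTACATTTCCCGATTGGCGGTGTAGCTATGCCGA
>C synthetic COI-COII spacer exemplar (non-empirical stand-in)
CGGCAAATTTAAGAGGCTTGCACGTCCGTCATCATCCCTCCTTAGAATCTAGGAGCAAAGTGGCGCGAGCCCTTCTACAATTAGTAACCGTCATCAAATGCCCCCGCATGTATTGCCAAGGATGATCGTGAAGATGGTGATCTGATCCAATCTGCCTATGAGAATGACAAACGGGGGGGGTATGTTCTACGTTTCCCGATTGGCGGTGTAGCTATGCCGC
>M synthetic COI-COII spacer exemplar (non-empirical stand-in)
CGGCAAATCCATGAGGCTGGCAAGTCCGTCGTCATCCTTCCTTTGTATCTAAGAGCAAAGTGGCACGCGCCCCTCTAAACTTAGTAATCGTTATGAAATGCCGACGCAGGTGCTGGCAGGGATTCTCGGTAAGATTCTGATCGGATCCAATCCGCCGATGAGAATGACAAACCGGGGCCTTATCTTTTACAGTTCGGCATTGGAGATGCTGCTATGCCGC
>O synthetic COI-COII spacer exemplar (non-empirical stand-in)
GGGGAAAGTCATGATGCTTGAAAGTCCGTCATCATCCCTCCTTTGTATCTAGGAGTACAGTGGCACGTGCCCCTCTACTCTTTGTAACAGTCATGAAATTCCCTCGAATGTGCTTCCAAGGATTTTAGGTAAGATGCTGATAGGATCCAATCCGCCTATGAGAATAACAAACCGGGGTGTTATGTTCTACGTTTCCCGATTGACGCTGTCCCTATGCCTC
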