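>LT1
GTGAACCCCCTGCACGCCCTAAAGTACAATTAGGATATTCATCCCTACAC
>LT2
TGTATATGCCGAACGTTCTAATAAACGACTTAGCAACAAGTCGCCTAGAA
>LT3
AGGTACCGCTGGCATATCACGCCTCCCGCTTGCCGTCTTCAACTTCATGA
>LT4
CCCTCGTGCATCACAAAGCCTCAAGCCGGAGTCTAGGCTTTGAAACAGCT
>LT5
GAATAAATCGTGTGAATACGTGAGTCGTCGGAAAGCAGTTGAATATCTAA
>LT6
CGACCCCTGCGCAAGGACACACTAGTCGCCCTTGAGAGCACTCCAGTCCA
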