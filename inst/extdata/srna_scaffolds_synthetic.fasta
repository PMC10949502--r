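>MicC synthetic-stand-in MicC-type Hfq-binding scaffold (constructed hairpin, not the natural E. coli MicC sequence)
TTTCTGGTAGCACCTGATGGGCCAAGGCCCATCAGGTGCTTTTTTAT
>DsrA synthetic-stand-in DsrA-type scaffold (constructed hairpin, not the natural E. coli DsrA sequence)
AACGAATTCCTGGTGCAACCTTGGCAGGTTGCACCTTTTTTGT
>MicF synthetic-stand-in MicF-type scaffold (constructed hairpin, not the natural E. coli MicF sequence)
GCTATCATCATTAACCGGTGTCTTGGCAGACACCGGTTTTTTTA
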