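>KSR3_3HA_FW triple-HA-tag forward oligonucleotide (sea urchin ksr3 fusion)
TACCCATACGATGTTCCAGATTACGCTGGCTATCCCTATGACGTCCCGGACTATGCAGGA
TATCCATATGACGTTCCAGATTACGCTATGCAACCAAAGGAACATATA
>KSR1_3HA_FW triple-HA-tag forward oligonucleotide (sea urchin ksr1 fusion)
TACCCATACGATGTTCCAGATTACGCTGGCTATCCCTATGACGTCCCGGACTATGCAGGA
TATCCATATGACGTTCCAGATTACGCTATGTCTGGAGATTGTTTATCGTC
>KSR3_NV_3HA triple-HA-tag forward oligonucleotide (cnidarian ksr3 fusion)
ACCATGTACCCATACGATGTTCCAGATTACGCTGGCTATCCCTATGACGTCCCGGACTAT
GCAGGATATCCATATGACGTTCCAGATTACGCTATGCAAGAGCCGTCTCACAGTTTC
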