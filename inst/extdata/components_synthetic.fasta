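>bsmbi_adapter_5
CAGATGACTCGTCTCGCACC
>trcRNA
GTTTTAGAGCTAGAAATAGCAAGTTAAAATAAGGCTAGTCCGTTATCAACTTGAAAAAGTGGCACCGAGTCGGTGC
>tRNA
AACAAAGCACCAGTGGTCTAGTGGTAGAATAGTACCCTGCCACGGTACAGACCCGGGTTCGATTCCCGGCC
>bsmbi_adapter_3
GTTTGGAGACGAAAGGGCCC
>primer_BsmBI-F
CAGATGACTCGTCTCGCACC
>primer_trc-tRNA-R
CTGGTGCTTTGTTGCACCGA
>primer_trc-tRNA-F
CCGAGTCGGTGCAACAAAGC
>primer_BsmBI-R
GGGCCCTTTCGTCTCCAAAC
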