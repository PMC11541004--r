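>synthetic_frpo_01
GCTCTGATAGGTAAAAAGTGTATTATGTTTGACAGGTACTTTTTGGAGCATATAATTGTGATTATATGCTCCAAAAAGTACCTGTCAAACATAATACACTTTTTACCTTCGTATCC
>synthetic_frpo_02
TGGGCGAAAATAAATTTTATTAATTTTATTGACACCCATCAGTCTCCCGGTATATAATACACATTATATACCGGGAGACTGATGGGTGTCAATAAAATTAATAAAATTTATTCGTGAACT
>synthetic_frpo_03
TTTTAAGATATAATTATAAAGAAATACATTGACACGGGTCATTTGTTAGTTATAATTTCGATTATAACTAACAAATGACCCGTGTCAATGTATTTCTTTATAATTATAACGTGGTT
>synthetic_frpo_04
TGTAGGTATTATATTAAAATGCTACTAATTGACACAGTCGATCGGTCCCTATAATTATAATTATAGGGACCGATCGACTGTGTCAATTAGTAGCATTTTAATATAAACGCGTTC
>synthetic_frpo_05
CTGTGCCGATATAATTTAATTTATAAATTTGACATGTCCGAACGAGTGACAATATAATACCCATTATATTGTCACTCGTTCGGACATGTCAAATTTATAAATTAAATTATATGTGGCTTT
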