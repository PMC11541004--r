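>synthetic_oriT_01
CGACCCGGTGTAAGATGCCTCACCAGTTACACTACGTTTATCCCAAGTGAGCTTATGCACTGCGCACAAGGTTGCTCCGACGCAACCTTGTGCTTACCTTGTGCGCGGCGTCTCACCGCAATCCTCCCCACATTGCCCGCCATTCTGGCCTCGTAAGCCCTCCCTCAAGAATCTCCCTTGAATCTCAGGAACTAAATTACGCAATCATACCGGAACGGCGATCA
>synthetic_oriT_02
TGTACTTTTAACTAAGCGGACTCATGATTGTACACGAGACCCGAAGGATTCTCCAGCCAATTATTGGTAGAATCCAATAATTGGCTCTTAGCAAGGACAGAGCGTTGCCAATATGCACGTCGTGTCTCCTACGTGTCCATCGCATGCCGGCTTTTGTTACGTTCTGAAACGCACGA
>synthetic_oriT_03
TTGAACGCCGACAAGCCACAGGGCCTTGTAACTGACGGCTTAACTGCTTCACATAGGAGCTAATCTTGTCATGGCGATCATGTGTTTTTTTCGGAAAACACATGATCTTTATCTAGTTTAGAGGTTGCGCGGCCACAAAATACGACACAACTGATTAGCATCTACGAGAGCCACCGGCACCGGGCGGGAGTAACTGGAGATAAGGCATGTGGGTCGTATACT
>synthetic_oriT_04
CTATTCTCAGGCGCAAGATTTGGAACCTAGTGTATCGTTGGGTAGGGATCCGGGATAGGTGGTCAGATTTCCCCTGTGGGAAATCTGACCACGGCTCAGCCTCGCCGAAACCGATGTATTAGACCGGTCCTGGAACAGTTTCTGCGCAGGCAAATATGACTTGAGACGCCACACCGATTAGAAGAC
>synthetic_oriT_05
AGGCATATCAGACACCGAGGTCCTGGGTGGTTATAGACCGATCATTTTAAAGTGGTGATAAATCAGTGTGACCTGATTTATCACGTCCGACGGGCGGAATCTTACTGTGCATTTGGGAACTATCTTCGAGTCGGCTCTCCATCTGCGAGTGATAGCCCCCTAGTGCTCCCACGCTTTTACGGC
>synthetic_oriT_06
CCAGATCGGATTATTTAGAAGCGCTCTAATTCGACGGCTCGATTAACCACATTAATCGGGGTGCGGGATGACGCACCCCGATTACAGAAAGAGATTTAGGACATATTCTGATTACGAAGAGTGTTTTGGTATATTGGAAAGGCGATCTTCGCCGTGGCCCAGAAGAGTATGGGTGCG
>synthetic_oriT_07
GTTACAGACAATAGGGAAAGTTACCGACCATGAGTTGATGAGGGCGCGGGGCCTGCACCCCAGGACTGCAGCTTCCGTAGCTCTTCACAAGTGTGCCCTTGTGAAGAGCGGAGCCTTGAGGACAAGTATGCCATTCTGTGTCGTAGGGCCTGCACTAGCGAAA
>synthetic_oriT_08
TGCTGGCTGATCGACTTATCCAAACCTCGGACTCAACGGATGACATCGCACCGCGTTATACCACTCATGCGATCTAGATTCCAATCTAGATCGCATCGCGCGGAAGTCATGCGGGAGCACATCAAAATTGCTATTCACTCTGTGAGCCTATAGGCTCGAATTTCAAGTTTTGGTGTCACGAGTAGACCCCTGGATC
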