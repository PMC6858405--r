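>seq01
GAGGTTACATTTCTAGGGACCGAACGTCTCCGGTCGTTATCCTCCAAAGCGGGACATACTTATAGTTCCTCACAATACGGATCATCACTAAAATACCGAAGTTTAGTCATACCTCATAAACCATTGGTCGACGTCTGGCGAGAGACCCCTGAGGCACGATACCAGAAGCCTTGGACATCGAAACCTGCCGGCCGTCTTAGACTCCCCCGTCCATTTTCGTCGGCACCTACCCGACCTGCAACAAATTTCGTATGTGCATACCTGTACACCGGAGTCACATGCTGTAGGCCCTGCGACCGACTGTTAAGATCCAGCCCATTCTATACAACCATCGCGGTGCACCTGGAACGCAAAGGCACAAGGTCGTGCCTACATTTTGAACGGCACAGTTGGTGCGCCAAACTGACGGATACAGCCACGGACCCCGCATTAATCCACATAGAATTTTGCCGTCCCCCTGACCCGCAATCTGGGGGAATGATTCCCATAACTGGAATATCGCGAATGCAAAGGGTGAAGGCGATGGTGCAGTTGAACACTTTGGTCGAGGCCTCGACGGGTATCGTACTTCTGTTTCGAACACAAAGGTGGTGTCACCTACTTATCTTCCTAAATAGCATAATAGGAATCAGAAATGGTGCATATGTGGACTGGGCCCATAGTCCGTCAGAGGGCTCAACAAGCTCATGCGATCGTAGGCCACCGGGTAGTCTTTTTATTAAGTATCCATTCGTCTCTCAAAACCGAAGCACGGCTGTAATGCAATGCTCCTTTACGGTCAAAGGAAAAGAGGCCACGACGCCCCCAGTGGGTCGCTGCCTTGCTCGTGTACACGCAACGTCAGCTAAGACTCCGGTAATGAAAGTAGAGTATAACCAAAGTGAGCCACCTGTTATAGGG
>seq02
GAGGTTACATTTCTAGGGACCGAACGTCTCCGGTCGTTATCCTCCAAAGCGGGACATACTTATAGTTCCTCACAATACGGATCATCACTAAAATACCGAAGTTTAGTCATACCTCATAAACCATTGGTCGACGTCTGGCGAGAGACCCCTGAGGCACGATACCAGAAGCCTTGGACATCGAAACCTGCCGGCCGTCTTAGACTCCCCCGTCCATTTTCGTCGGCACCTACCCGACCTGCAACAAATTTCGTATGTGCATACCTGTACACCGGAGTCACATGCTGTAGGCCTTGCGACCGACTGTTAAGATCCAGCCCATTCTATACAACCATCGCGGTGCACCTGGAACGCAAAGGCACAAGGTCGTGCCTACATTTTGAACGGCACAGTTGGTGCGCCAAACTGACGGATACAGCCACGGACCCCGCATTAATCCACATAGAATTTTGCCGTCCCCCTGACCCGCAATCTGGGGGAATGATTCCCATAACTGGAATATCGCGAATGCAAAGGGTGAACGCGATGGTGCAGTTGAACACTTTGGTCGAGGCCTCGACGGGTATCGTACTTCTGTTTCGAACACAAAGGTGGTGTCACCTACTTATCTTCTTAAATAGCATAATAGGAATCAGAAATGGTGCATATGTGGACTGGGCCCATAGTCCGTCAGAGGGCTCAACAAGCTCATGCGATCGTAGGCCACCGGGTAGTCTTTTTATTAAGTATCCATTCGTCTCTCAAAACCGAAGCACGGCTGTAATGCAATGCTCCTTTACGGTCAAAGGAAAAGAGGCCACGACGCCCCCAGTGGGTCGCTGCCTTGCTCGTGTACACGCAACGTCAGCTAAGACTCCGGTAATGAAAGTAGAGTATAACCAAAGTGAGCCACCTGTTATAGGG
>seq03
GAGGTTACATTTCTAGGGACCGAACGTCTCCGGTCGTTATCCTCCAAAGCGGGACATACTTATAGTTCCTCACAATACGGATCATCACTAAAATACCGAAGTTTAGTCATACCTCATAAACCATTGGTCGACGTCTGGCGAGAGACCCCTGAGGCACGATACCAGAAGCCTTGGACATCGAAACCTGCCGGCCGTCTTAGACTCCCCCGTCCATTTTCGTCGGCACCTACCCGACCTGCAACAAATTTCGTATGTGCATACCTGTACACCGGAGTCACATGCTGTAGGCCCTGCGACCGACTGTTAAGATCCAGCCCATTCTATACAACCATCGCGGTGCACCTGGAACGCAAAGGCACAAGGTCGTGCCTACATTTTGAACGGCACAGTTGGTGCGCCAAACTGACGGATACAGCCACGGACCCTGCATTAATCCACATAGAATTTTGCCGTCCCCCTGACCCGCAATCAGGGGGAATGATTCCCATAACTGGAATATCGCGAATGCAAAGGGTGAAGGCGATGGTGCAGTTGAACACTTTGGTCGAGGCCTCGACGGGTATCGTACTTCTGTTTCGAACACAAAGGTGGTGTCACCTACTTATCTTCTTAAATAGCATAATAGGAATCAGAAATGGTGCATATGTGGACTGGGCCCATAGTCCGTCAGAGGGCTCAACAAGCTCATGCGATCGTAGGCCACCGGGTAGTCTTTTTATTAAGTATCCATTCGTCTCTCAAAACCGAAGCACGGCTGTAATGCAATGCTCCTTTACGGTCAAAGGAAAAGAGGCCACGACGCCCCCAGTGGGTCGCTGCCTTGCTCGTGTACACGCAACGTCAGCTAAGACTCCGGTAATGAAAGTAGAGTATAACCAAAGTGAGCCACCTGTTATAGGG
>seq04
GAGGTTACATTTCTAGGGACCGAACGTCTCCGGTCGTTATCCTCCAAAGCGGGACATACTTATAGTTCCTCACAATACGGATCATCACTAAAATACCGAAGTTTAGTCATACCTCATAAACCATTGGTCGACGTCTGGCGAGAGACCCCTGAGGCACGATACCAGAAGCCTTGGACATCGAAACCTGCCGGCCGTCTTAGACTCCCCCGTCCATTTTCGTCGGCACCTACCCGACCTGCAACAAATTTCGTATGTGCATACCTGTACACCGGAGTCACATGCTGTAGGCCCTGCGACCGACTGTTAAGATCCAGCCCATTCTATACAACCATCGCGGTGCACCTGGAACGCAAAGGCACAAGGTCGTGCCTACATTTTGAACGGCACAGTTGGTGCGCCAAACTGACGGATACAGCCACGGACCCTGCATTAATCCACATAGAATTTTGCCGTCCCCCTGACCCGCAATCTGGGGGAATGATTCCCATAACTGGAATATCGCGAATGCAAAGGGTGAAGGCGATGGTGCAGTTGAACACTTTGGTCGAGGCCTCGACGGGTATCGTACTTCTGTTTCGAACACAAAGGTGGTGTCACCTACTTATCTTCTTAAATAGCATAATAGGAATCAGAAATGGTGCATATGTGGACTGGGCCCATAGTCCGTCAGAGGGCTCAACAAGCTCATGCGATCGTAGGCCACCGGGTAGTCTTTTTATTAAGTATCCATTCGTCTCTCAAAACCGAAGCACGGCTGTAATGCAATGCTCCTTTACGGTCAAAGGAAAAGAGGCCACGACGCCCCCAGTGGGTCGCTGCCTTGCTCGTGTACACGCAACGTCAGCTAAGACTCCGGTAATGAAAGCAGAGTATAACCAAAGTGAGCCACCTGTTATAGGG
>seq05
GAGGTTACATTTCTAGGGACCGAACGTCTCCGGTCGTTATCCTCCAAAGCGGGACATACTTATAGTTCCTCACAATACGGATCATCACTAAAATACCGAAGTTTAGTCATACCTCATAAACCATTGGTCGACGTCTGGCGAGAGACCCCTGAGGCACGATACCAGAAGCCTTGGACATCGAAACCTGCCGGCCGTCTTAGACTCCCCCGTCCATTTTCGTCGGCACCTACCCGACCTGCAACAAATTTCGTATGTGCATACCTGTACACCGGAGTCACATGCTGTAGGCCCTGCGACCGACTGTTAAGATCCAGCCCATTCTATACAACCATCGCGGTGCACCTGGAACGCAAAGGCACAAGGTCGTGCCTACATTTTGAACGGCACAGTTGGTGCGCCAAACTGACGGATACAGCCACGGACCCCGCATTAATCCACATAGAATTTTGCCGTCCCCCTGACCCGCAATCTGGGGGAATGATTCCCATAACTGGAATATCGCGAATGCAAAGGGTGAACGCGATGGTGCAGTTGAACACTTTGGTCGAGGCCTCGACGGGTATCGTACTTCTGTTTCGAACACAAAGGTGGTGTCACCTACTTATCTTCCTAAATAGCATAATAGGAATCAGAAATGGTGCATATGTGGACTGGGCCCATAGTCCGTCAGAGGGCTCAACAAGCTCATGCGATCGTAGGCCACCGGGTAGTCTTTTTATTAAGTATCCATTCGTCTCTCAAAACCGAAGCACGGCTGTAATGCAATGCTCCTTTACGGTCAAAGGAAAAGAGGCCACGACGCCCCCAGTGGGTCGCTGCCTTGCTCGTGTACACGCAACGTCAGCTAAGACTCCGGTAATGAAAGCAGAGTATAACCAAAGTGAGCCACCTGTTATAGGG
>seq06
GAGGTTACATTTCTAGGGACCGAACGTCTCCGGTCGTTATCCTCCAAAGCGGGACATACTTATAGTTCCTCACAATACGGATCATCACTAAAATACCGAAGTTTAGTCATACCTCATAAACCATTGGTCGACGTCTGGCGAGAGACCCCTGAGGCACGATACCAGAAGCCTTGGACATCGAAACCTGCCGGCCGTCTTAGACTCCCCCGTCCATTTTCGTCGGCACCTACCCGACCTGCAACAAATTTCGTATGTGCATACCTGTACACCGGAGTCACATGCTGTAGGCCTTGCGACCGACTGTTAAGATCCAGCCCATTCTATACAACCATCGCGGTGCACCTGGAACGCAAAGGCACAAGGTCGTGCCTACATTTTGAACGGCACAGTTGGTGCGCCAAACTGACGGATACAGCCACGGACCCTGCATTAATCCACATAGAATTTTGCCGTCCCCCTGACCCGCAATCTGGGGGAATGATTCCCATAACTGGAATATCGCGAATGCAAAGGGTGAAGGCGATGGTGCAGTTGAACACTTTGGTCGAGGCCTCGACGGGTATCGTACTTCTGTTTCGAACACAAAGGTGGTGTCACCTACTTATCTTCCTAAATAGCATAATAGGAATCAGAAATGGTGCATATGTGGACTGGGCCCATAGTCCGTCAGAGGGCTCAACAAGCTCATGCGATCGTAGGCCACCGGGTAGTCTTTTTATTAAGTATCCATTCGTCTCTCAAAACCGAAGCACGGCTGTAATGCAATGCTCCTTTACGGTCAAAGGAAAAGAGGCCACGACGCCCCCAGTGGGTCGCTGCCTTGCTCGTGTACACGCAACGTCAGCTAAGACTCCGGTAATGAAAGTAGAGTATAACCAAAGTGAGCCACCTGTTATAGGG
>seq07
GAGGTTACATTTCTAGGGACCGAACGTCTCCGGTCGTTATCCTCCAAAGCGGGACATACTTATAGTTCCTCACAATACGGATCATCACTAAAATACCGAAGTTTAGTCATACCTCATAAACCATTGGTCGACGTCTGGCGAGAGACCCCTGAGGCACGATACCAGAAGCCTTGGACATCGAAACCTGCCGGCCGTCTTAGACTCCCCCGTCCATTTTCGTCGGCACCTACCCGACCTGCAACAAATTTCGTATGTGCATACCTGTACACCGGAGTCACATGCTGTAGGCCTTGCGACCGACTGTTAAGATCCAGCCCATTCTATACAACCATCGCGGTGCACCTGGAACGCAAAGGCACAAGGTCGTGCCTACATTTTGAACGGCACAGTTGGTGCGCCAAACTGACGGATACAGCCACGGACCCCGCATTAATCCACATAGAATTTTGCCGTCCCCCTGACCCGCAATCTGGGGGAATGATTCCCATAACTGGAATATCGCGAATGCAAAGGGTGAAGGCGATGGTGCAGTTGAACACTTTGGTCGAGGCCTCGACGGGTATCGTACTTCTGTTTCGAACACAAAGGTGGTGTCACCTACTTATCTTCCTAAATAGCATAATAGGAATCAGAAATGGTGCATATGTGGACTGGGCCCATAGTCCGTCAGAGGGCTCAACAAGCTCATGCGATCGTAGGCCACCGGGTAGTCTTTTTATTAAGTATCCATTCGTCTCTCAAAACCGAAGCACGGCTGTAATGCAATGCTCCTTTACGGTCAAAGGAAAAGAGGCCACGACGCCCCCAGTGGGTCGCTGCCTTGCTCGTGTACACGCAACGTCAGCTAAGACTCCGGTAATGAAAGCAGAGTATAACCAAAGTGAGCCACCTGTTATAGGG
>seq08
GAGGTTACATTTCTAGGGACCGAACGTCTCCGGTCGTTATCCTCCAAAGCGGGACATACTTATAGTTCCTCACAATACGGATCATCACTAAAATACCGAAGTTTAGTCATACCTCATAAACCATTGGTCGACGTCTGGCGAGAGACCCCTGAGGCACGATACCAGAAGCCTTGGACATCGAAACCTGCCGGCCGTCTTAGACTCCCCCGTCCATTTTCGTCGGCACCTACCCGACCTGCAACAAATTTCGTATGTGCATACCTGTACACCGGAGTCACATGCTGTAGGCCTTGCGACCGACTGTTAAGATCCAGCCCATTCTATACAACCATCGCGGTGCACCTGGAACGCAAAGGCACAAGGTCGTGCCTACATTTTGAACGGCACAGTTGGTGCGCCAAACTGACGGATACAGCCACGGACCCCGCATTAATCCACATAGAATTTTGCCGTCCCCCTGACCCGCAATCTGGGGGAATGATTCCCATAACTGGAATATCGCGAATGCAAAGGGTGAAGGCGATGGTGCAGTTGAACACTTTGGTCGAGGCCTCGACGGGTATCGTACTTCTGTTTCGAACACAAAGGTGGTGTCACCTACTTATCTTCTTAAATAGCATAATAGGAATCAGAAATGGTGCATATGTGGACTGGGCCCATAGTCCGTCAGAGGGCTCAACAAGCTCATGCGATCGTAGGCCACCGGGTAGTCTTTTTATTAAGTATCCATTCGTCTCTCAAAACCGAAGCACGGCTGTAATGCAATGCTCCTTTACGGTCAAAGGAAAAGAGGCCACGACGCCCCCAGTGGGTCGCTGCCTTGCTCGTGTACACGCAACGTCAGCTAAGACTCCGGTAATGAAAGCAGAGTATAACCAAAGTGAGCCACCTGTTATAGGG
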