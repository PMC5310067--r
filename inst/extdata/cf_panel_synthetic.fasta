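>ATF1 chr12:50764850-50765098 synthetic
CTGCCGGTGGATGTTGTATGCCGGACGAAGGTAAACGCCGCGGAACCGGTGGTTCTGCGACTACCGCCTCGCGGGCGATTAAGGAATGTTTACAGGACAACTAGCACAAAATGCTGGAGTGGACAAGGAACCTCAATTCAATTGTATGATTAGAGAATTAGGCCTGGAAGAATGGTTGACTTATTAAAAGTGGTGCCCTGGTGTTGAAGACTTCCAGTCTTTTCAGATTGAGAGCTGAGGTGCATCAGA
>CFTR chr7:117479627-117479759 synthetic
ACCGTTACGATTGAAGTTTGCCGTCGAGGCGCGTGACATCCGTTGCGATGCGCGCAATCATGTGGGAGTGTTTTGCCCTGGCTCCTGGGGCACTGGAATGAATAATATGCTGCTGTTTGCTTGCCTTCCTGTA
>DUOX2 chr15:45114541-45114722 synthetic
TGCGCGACGACGACATCTGGCGCGCTAAGTCGTGACACGGCCAGGTGCGTGTCCTGGTGCGCAAATGGTGGAATAGCGTTCCACCTTTGTGACTGTACTTACAACTCCTGTTAGTCCACAGCTGTACCTAATGGTTGTGCTCAGGCAAGTGTGTTTATCCCAATCTACTCCCACCTCCTAAA
>EDNRA chr4:147480957-147481216 synthetic
TAACGAGACCATGTACCTGGACGTGGCCGCGATCCCTCGATAGTGCGCAGTTTTCGCGGTCACCCACGCGCCTTGCGCACCGGATCGGGTACGTCGAAGGTGGGCGCATGCGTGAACGTAATTCGTGCCGCGACTAACAACCTTTAGTGGTGGTAGGCTGTCAAGCTTAAATCTGTCTGGACCTAAGAGAAGAGCCTTCATGGGTACTGGTTAGGGTAATTGTGAGATCAGGTGAATCTTTAAGGCTCCATGCCCACCTG
>SCNN1G chr16:23182420-23182665 synthetic
CGGAGAACGTGGCTTCCGTACTTGTCTGAGTTCATCGGACGTCGACGCCGATCGGCGGTGATGGCACCACTCAACGCAGGTCCGTCGCGGGCCGGCCCCGGGCGAAACCGGGCAGCCGCGTCGACGAGCGCTGTACTTTGTTGTTTGTGTGATTATCAATACATACTGTTACTGCAAAGCAAGTGTAGGTGATTTGCTTGACTGTAAGATCTGCCAATTATGGTGGCCACAGTTGTTTCTGAAATG
>GSTM1 chr1:109687687-109687897 synthetic
AGCCGAATCCGTTGCGACGTTGGTCGGTTTTGATGTGCGCGCGTTGAGGCCGCGTACGCAAAAACGGGCCTCGTGTAAGTGTTGAGGGAGGTCTCATACTTCCTACCAGTGAAGGTGGGTGTGTGCCAATTTAGCATAAGTATCATCCTCAGGTAAAAAATATTGGGGTGGAAAGTGCACTATGCACCAACTAGGAATCAATACAAAATTG
>GSTM3 chr1:109740573-109740793 synthetic
AACGGCGGTTCGGCCGGTGGCTCGCACTCAACCTTCGTGCGATGCCGAATCAATCACGTAAAATTGTAGACTGCTCTGCTTTCTGAGGGTTCTGTCCTTATTGCTGTGAACCTTTTGGTATGGTGTTTGCTGTGCATACTCTGATTTCTAGCCCCTACAACCTATTACTAACTGGCTTGCTTGGCACCATCATACTGTGACCCTGATGGGGTACATCTTAG
>HMOX1 chr22:35381269-35381436 synthetic
TGATGTCACAGCGAATTTCTTGATTCACGCACTGCGTGGTGTATGACCGTGGCACCCACGGCTTACCTATTAATTATAGATTCACTGAATGAATAGTTGGGCCTTGTGCTCTCCCCCACAGCAGGCACCTGCTGTCAGCTCATGTAGGCCAATGCTATGTGTGTGTAC
>IFRD1 chr7:112450883-112451040 synthetic
CGTACGGTGCCCGACGGCGATGCGCAGGTGGGGCACGCGTCGAGGCCGTGGCCACGTTCACCGCAATGGACTGGGTGGATAAACTGTGGATGTACCTGTCTGAGTTGGTGTTGGCACATGTTGTCTAATAGTGGATTATAACCTTTGGAGCCAGCTGA
>MUC5AC chr11:1194622-1194807 synthetic
CGGCGACGGCTTTACGCGGCGAGACTGTTCCCGGGATGTGAACCGACGGGCGCGATACTACGACTGGCGGAGTCCAATTTCAGTGTGAATTGGATATGCCCAGGCTTTATGATACTATGATCTAATCTATATTGAGTATTCAAGTCTGGTGTCTCAGTATTGATTTAGCAAGCTGTATACTAGGGC
>TGFB1 chr19:41353542-41353740 synthetic
CCCGAAGACGGCGACGTTGCGGCGGGCGACGCACGAACCTTGCTCGTGGGCGCCCCGCGACGACTGGTGGTCGACTGCTTGCGGCCGGCGCACGGGCATGGTTCATTCTATAAACATGGTATATCTATTGCTATGTCTTGCTGTCACTCCAATGGGAGGCTGCTGAGTGCTTTGTCCATTTTCCACAAAAGCATAATAT
>TLR2 chr4:153684576-153684704 synthetic
CGTGACTATCCGTTCGAGCGCGCGATCCAGTAGGTTACGGACTGCGGGCGCGCCGCGCATCTGGCTTAGATCCATGAACATGGCCTCTCAAGAAAGAGTAGGGAATGGGAACAGCTCTGCTCAAGTTGG
>TLR5 chr1:223142813-223142967 synthetic
CTACGATCGACTATCGCTAGCCGTGTGTGCGGCCCTGCATCACCCGAGTTTCCTGACACGCTCGAGCACAGACTGGACATACAAGGCTTGTTTGAGTCTGGCTCTTGTCATTGCTGCTTCTTTGTCTCTTGTAAATGCTCAGCAACAAATCTGCA
>YY1 chr14:100240497-100240751 synthetic
CCGTCGTTTATGATACCGGTCGTGTGTTCGCGGCTCGCTTGCGAGACGGAGCGTAGAACGCGCAGCCGCGGGACTCCGACGACTATATAAGGGCGGCGATGTATGACGGAACAGCCCGTGCGCTACGGCCCCCGCGCGCGATTATGGAATGTGTGTGCATCAACCCCTGATAATGGTCAACCTCCTGGTGAGCTACAACAGGGAGATAACCCCCCAGGTACTCTGCCCATAGTATAGCAACTGCTAAAAAGAACA
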