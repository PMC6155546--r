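record_id	taxonomy	gene	sequence
CMTALT10	Bacteria;Firmicutes;Bacilli;Lactobacillales;Lactobacillaceae;Lactobacillus;Lactobacillus algidus;CMTALT10	gyrB	AGACCAGCAATGTACATAGGGGGTGCGAGGTTTTTCGTGGCAATAGAGGTATCGCAGTGCACTAAACCCTACGAAGCGCCTCTAGCAGCGACGGAGCGGTACCCTGTGACGGGCGTGAGGAATTTCAACCAAACTGAGTTTCAGGAGGACTACACGGAG
CMTALT10	Bacteria;Firmicutes;Bacilli;Lactobacillales;Lactobacillaceae;Lactobacillus;Lactobacillus algidus;CMTALT10	parE	AGACCAGCAATGTACATAGGGAGTGAAAGGTTGTACGGTGCAGCTCCGGAATTACACTTTACCAGGGACCCCAGACCGGCTCACTAAGCAACGCGGGGGGGTCGCGGGACATTGTGAGTGTCCTTATCCAAAAATGTATTTCAGGAGGACTACACGGAG
23K	Bacteria;Firmicutes;Bacilli;Lactobacillales;Lactobacillaceae;Lactobacillus;Lactobacillus sakei;23K	gyrB	AGACCAGCAATGTACATAGGAGGTACTAGGTTTTTCGTGGAAACAGAGGAATCGGATAACACCAAACACGCCGAAACCCCTTTATCAGCGCCGGAGTGGTATCGTGCGACAGGAGTGAAGACTGTCAGCGATACTGAGCTTCAGGAGGACTACACGGAG
23K	Bacteria;Firmicutes;Bacilli;Lactobacillales;Lactobacillaceae;Lactobacillus;Lactobacillus sakei;23K	parE	AGACCAGCAATGTACATAGGGAGAGCAAGGTTGTACGGTGCAGCAACAGTACCACTCTTTACCAGAGACGCTAGACCGGGGCCCTGAGCGACGCGGCGGGATTGTAGGACTTTTGTAGACTCCATAACTGGAACTGGATTTCAGGAGGACTACACGGAG
CMTALT02	Bacteria;Firmicutes;Bacilli;Lactobacillales;Streptococcaceae;Lactococcus;Lactococcus piscium;CMTALT02	gyrB	AGACCAGCAATGTACATAGGGCGTACAAGGTTTTTCGTGGCAACTGAAGAATCGCAGTACACCAAATACGCCTCCACGCCTCTATCAGCGGCTGTGGGGTATCGTGCGACGGGTATGAGGACTTTCCCCCACACTGAATGTCAGGAGGACTACACGGAG
CMTALT02	Bacteria;Firmicutes;Bacilli;Lactobacillales;Streptococcaceae;Lactococcus;Lactococcus piscium;CMTALT02	parE	AGACCAGCAATGTACATAGGCATTACAAGGTAGTAGGGTTCAGCAACGGCATCACACTTTACCAGAGACCCCAGACCGGCTCCCTGAACAACCCGTCCGGATCCTGGAACATTTATAGATTCCATATCAGAATGTGCATTTCAGGAGGACTACACGGAG
160x8	Bacteria;Firmicutes;Bacilli;Bacillales;Listeriaceae;Brochothrix;Brochothrix thermosphacta;160x8	gyrB	AGACCAGCAATGTACATAGGGGCTGAAAGGTTGTTCGTTGCAACAGAGCAATCGCAGTACACCTAACAAGCCGAATCGCCTCTGTCAGCGCCGGAGGGGGACCCTGCCTCGGGTGGGAGGACTTTCACCGAAACCGAGTTTCAGGAGGACTACACGGAG
160x8	Bacteria;Firmicutes;Bacilli;Bacillales;Listeriaceae;Brochothrix;Brochothrix thermosphacta;160x8	parE	AGACCAGCAATGTACATAGGGGGTGAGACGTTGTACGGGGCAGAAACGGAAACTCACTTGACCACCGACCCCAGACAGGCTCCCTGCCTAACGAGGCGGGATCGTGGGACCTTTATGGAGTCCATATCCGAAACTGGATTTCAGGAGGACTACACGGAG
MFPA43A14-05	Bacteria;Firmicutes;Bacilli;Lactobacillales;Carnobacteriaceae;Carnobacterium;Carnobacterium divergens;MFPA43A14-05	gyrB	AGACCAGCAATGTACATAGGGTGTACCAGGTTTTTCTTGGCCACAGAAGAATTGCAGTACACAAAACACGCCGGAACGCCACCCTCAGCGACGGATCGGTATCGTGCCACGGGTGTGGGGACTTTCACTGAAACTGTGCTTCAGGAGGACTACACGGAG
MFPA43A14-05	Bacteria;Firmicutes;Bacilli;Lactobacillales;Carnobacteriaceae;Carnobacterium;Carnobacterium divergens;MFPA43A14-05	parE	AGACCAGCAATGTACATAGGGAGGGCATGGTTGTACTGTGCAGCAACGGAATCACACTTTACCAGAGACCCCAGCTCGGCCCCGTGAGGAAGGCGGCCAGTTCGGGGGCCATTTATAGAGTTCTTATCTGAAACCGGATTTCAGGAGGACTACACGGAG
DSM20342	Bacteria;Firmicutes;Bacilli;Lactobacillales;Carnobacteriaceae;Carnobacterium;Carnobacterium maltaromaticum;DSM20342	gyrB	AGACCAGCAATGTACATAGGGGCTACAAGATTTTTCGTGGCAACAGAGGAATCAGAGTGGAGCAAACACGCCGAATCGTCTCTATCAGCTACTGGGTGGAATCGTGCGACGGGTGTGATCACTTTCTCCGAGACTGAGGTTCAGGAGGACTACACGGAG
DSM20342	Bacteria;Firmicutes;Bacilli;Lactobacillales;Carnobacteriaceae;Carnobacterium;Carnobacterium maltaromaticum;DSM20342	parE	AGACCAGCAATGTACATAGGGCGAGGAAAGTTGTACGGTGCAACAACGGAATGACTCTTTACCAGAGACCGGAGACCGGCTCCCTGAGCGACGCCGCGGGATCGTGGAACGTGTCTAGACCCAATATCCGAAACTGGATTTCAGGAGGACTACACGGAG
MFPA44A14-01	Bacteria;Firmicutes;Bacilli;Lactobacillales;Leuconostocaceae;Leuconostoc;Leuconostoc gelidum;MFPA44A14-01	gyrB	AGACCAGCAATGTACATAGGGGGTACAAGATTATAACTGGCAACATAGGGATTGCAGTACACTAAACAAGCCGAATCGCATCTATTAGCGACGGAGCGGTATCGTGCGACGGGTGGGAGGACGTTCACCGGGAGTGAATTTCAGGAGGACTACACGGAG
MFPA44A14-01	Bacteria;Firmicutes;Bacilli;Lactobacillales;Leuconostocaceae;Leuconostoc;Leuconostoc gelidum;MFPA44A14-01	parE	AGACCAGCAATGTACATAGGGCGTGCAAGTTTGTACGTTGCAGCAACGGAATCACACATTACCAGAGGCCCCAGAAAGACGCCCTGAGCAACGTGGCGGGATCCTGGGACATTTATAGATTTGATATCCCAACCTGAATATCAGGAGGACTACACGGAG
MFPC16A28-05	Bacteria;Firmicutes;Bacilli;Lactobacillales;Leuconostocaceae;Weissella;Weissella viridescens;MFPC16A28-05	gyrB	AGACCAGCAATGTACATAGGGAGTAAAAGGTTCTTCGTGGCGACAGACGAATCGCATTTCAGCAAACACGACCAATCGCCTCTATCTACTACGGGCCGGTATCGTGGGACAGGTGTGAGGACTTTCACCGAAACTGAATTTCAGGAGGACTACACGGAG
MFPC16A28-05	Bacteria;Firmicutes;Bacilli;Lactobacillales;Leuconostocaceae;Weissella;Weissella viridescens;MFPC16A28-05	parE	AGACCAGCAATGTACATAGGGAGTGCCGGGTTTTACGGTGCAGCAAATAAATCACGCTTTACCAGACACGCCAGACCGGCCCTCTCAGCCAAGCGACGGGATCGTGGTCCATTTATAGAGTCCAGATCCGAAACTGGATTTCAGGAGGACTACACGGAG
ATCC4973	Bacteria;Proteobacteria;Gammaproteobacteria;Pseudomonadales;Pseudomonadaceae;Pseudomonas;Pseudomonas fragi;ATCC4973	gyrB	AGACCAGCAATGTACATAGGGAGCCGATCCATTTAGCCGATGGGATCGGCCACTCATTGCAGTCCAAAATGAATCGTTTACAGTCAGAGAAACATAGAACTGTCTAGATCCACGACCTCCCTTGTCAAAGGTAAGTCACCTCAGGAGGACTACACGGAG
MFPA15A12-05	Bacteria;Proteobacteria;Gammaproteobacteria;Pseudomonadales;Pseudomonadaceae;Pseudomonas;Pseudomonas lundensis;MFPA15A12-05	gyrB	AGACCAGCAATGTACATAGGGAGCCGTACCATGTGGGCGAGCGGAGCAGCCACTCATTCGCGTCCAACTTGAATCGTCACAGGTCAGAGAGACATAGAACTGTCGAGGCCCATTACCGCCCTTGAGAAAAATAAGACACATCAGGAGGACTACACGGAG
MFPA43A14-04	Bacteria;Proteobacteria;Gammaproteobacteria;Pseudomonadales;Moraxellaceae;Acinetobacter;Acinetobacter guillouiae;MFPA43A14-04	gyrB	AGACCAGCAATGTACATAGGGACCCGTTCGATTCGGCCGAGCGGCGCACCCACTCACTCCAGTCCAGGATGAATCGTGACCATTCAAAGCGACAAAGAATTGTCTAGAGCCATTACCTCTCCTGAGAAATTTAAGTCACCTCAGGAGGACTACACGGAG
CIP105612	Bacteria;Proteobacteria;Gammaproteobacteria;Vibrionales;Vibrionaceae;Photobacterium;Photobacterium phosphoreum;CIP105612	gyrB	AGACCAGCAATGTACATAGGTACCCGTGCCATTTGGCCTAGCGGACCAGTCACTCATTGCGGTCCCACTTGAATCTTCAACAGGCAGGGAGACAAAGAACCGTCTAGATCAATTACCTCTCTTGAGAGATGTAAGTCACGTCAGGAGGACTACACGGAG
MFPA44A14-05	Bacteria;Proteobacteria;Gammaproteobacteria;Enterobacterales;Yersiniaceae;Serratia;Serratia proteamaculans;MFPA44A14-05	gyrB	AGACCAGCAATGTACATAGGGAGCCGTTACATGTGGCCGAGCGGACCAGCCACTCTAACCAGTCCAACAAGAAACGGCAGCAGTCAGATAGACTAAGAACTGTCAAGATGGATAAACTCCCTTGAGAAATGGAAGTTACCTCAGGAGGACTACACGGAG
CIP57.31	Bacteria;Proteobacteria;Gammaproteobacteria;Enterobacterales;Hafniaceae;Hafnia;Hafnia alvei;CIP57.31	gyrB	AGACCAGCAATGTACATAGGAAGCCGTTCCATTTAGCAGAGCCGACCAGCGACTCATATCAGTCCATCATGAATCGACACCAGTCAGAGAGACAAAGATCTGCCGAGACCCATTACCTTCCTTGAGAAATGTAACTCGTGTCAGGAGGACTACACGGAG
MFPA43A14-03	Bacteria;Proteobacteria;Gammaproteobacteria;Enterobacterales;Morganellaceae;Morganella;Morganella psychrotolerans;MFPA43A14-03	gyrB	AGACCAGCAATGTACATAGGGAGCCGCTCCAATTGGCCGGGCGGACCAGCAACTCATTCCAGTCCTAACTGAATCGTCACGAGTCGTGGAGACAAAGAACTGTCTGCATTCATTTCCACCCTTGAGAAACGTAAGTAACCTCAGGAGGACTACACGGAG
23K	Bacteria;Firmicutes;Bacilli;Lactobacillales;Lactobacillaceae;Lactobacillus;Lactobacillus sakei;23K	gyrB_fragment	GTTTTTCGTGGCAATAGAGGTATCGCAGTGCACTAAACCCTACGAAGCGCCTCTAGCAGCGACGGAGCGGTACCCTGTGACGGGCGTGAGG
23K	Bacteria;Firmicutes;Bacilli;Lactobacillales;Lactobacillaceae;Lactobacillus;Lactobacillus sakei;23K	recA	CCACTTAATGAGGGCACGCGAGTAACGTAAACTGATGGCGTCACCGACCTCTTGCTAGAATTGGGTGTTCACTGCGAGTCGTAAATCTCAGCGTTCACCGGAAATGAGCAAGTCGGGAAGGACTACTCCCTTTGGGGGGAGGAGACATGG
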