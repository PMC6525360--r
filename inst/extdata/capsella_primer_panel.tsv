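amplicon_id	direction	het_base	tail_seq	gene_seq
1	forward	none	TCGTCGGCAGCGTCAGATGTGTATAAGAGACAG	CCACTCATCCATTCGGAAAT
1	reverse	none	GTCTCGTGGGCTCGGAGATGTGTATAAGAGACAG	TTGGGGACAAGGTGCTAATC
1	forward	A	TCGTCGGCAGCGTCAGATGTGTATAAGAGACAG	CCACTCATCCATTCGGAAAT
1	reverse	A	GTCTCGTGGGCTCGGAGATGTGTATAAGAGACAG	TTGGGGACAAGGTGCTAATC
2	forward	none	TCGTCGGCAGCGTCAGATGTGTATAAGAGACAG	TACCGACCACATAGGCATCA
2	reverse	none	GTCTCGTGGGCTCGGAGATGTGTATAAGAGACAG	AATGGCCGATTCTGCTTTTA
2	forward	T	TCGTCGGCAGCGTCAGATGTGTATAAGAGACAG	TACCGACCACATAGGCATCA
2	reverse	T	GTCTCGTGGGCTCGGAGATGTGTATAAGAGACAG	AATGGCCGATTCTGCTTTTA
3	forward	none	TCGTCGGCAGCGTCAGATGTGTATAAGAGACAG	CAAGCCAAAGTTTGATGCTT
3	reverse	none	GTCTCGTGGGCTCGGAGATGTGTATAAGAGACAG	ACTCGTCTGCAGTCATGGTG
3	forward	A	TCGTCGGCAGCGTCAGATGTGTATAAGAGACAG	CAAGCCAAAGTTTGATGCTT
3	reverse	A	GTCTCGTGGGCTCGGAGATGTGTATAAGAGACAG	ACTCGTCTGCAGTCATGGTG
4	forward	none	TCGTCGGCAGCGTCAGATGTGTATAAGAGACAG	GGAAGCGGATGGTTACAAAA
4	reverse	none	GTCTCGTGGGCTCGGAGATGTGTATAAGAGACAG	AGGCCAAGCTCACTCACATT
4	forward	T	TCGTCGGCAGCGTCAGATGTGTATAAGAGACAG	GGAAGCGGATGGTTACAAAA
4	reverse	T	GTCTCGTGGGCTCGGAGATGTGTATAAGAGACAG	AGGCCAAGCTCACTCACATT
5	forward	none	TCGTCGGCAGCGTCAGATGTGTATAAGAGACAG	TGGGTTCAGATTGAGCGTAA
5	reverse	none	GTCTCGTGGGCTCGGAGATGTGTATAAGAGACAG	AACTTGATCCTCTTTGGTACTGG
5	forward	A	TCGTCGGCAGCGTCAGATGTGTATAAGAGACAG	TGGGTTCAGATTGAGCGTAA
5	reverse	A	GTCTCGTGGGCTCGGAGATGTGTATAAGAGACAG	AACTTGATCCTCTTTGGTACTGG
6	forward	none	TCGTCGGCAGCGTCAGATGTGTATAAGAGACAG	TTCTTTTTCTGAGATTCCATTGCT
6	reverse	none	GTCTCGTGGGCTCGGAGATGTGTATAAGAGACAG	AGAAGCCTCTCCTGAGAAGTGA
6	forward	T	TCGTCGGCAGCGTCAGATGTGTATAAGAGACAG	TTCTTTTTCTGAGATTCCATTGCT
6	reverse	T	GTCTCGTGGGCTCGGAGATGTGTATAAGAGACAG	AGAAGCCTCTCCTGAGAAGTGA
7	forward	none	TCGTCGGCAGCGTCAGATGTGTATAAGAGACAG	TCCAAGATCTGTGCTTGCTG
7	reverse	none	GTCTCGTGGGCTCGGAGATGTGTATAAGAGACAG	TCAGCTCCGGATGGTTAAAT
7	forward	A	TCGTCGGCAGCGTCAGATGTGTATAAGAGACAG	TCCAAGATCTGTGCTTGCTG
7	reverse	A	GTCTCGTGGGCTCGGAGATGTGTATAAGAGACAG	TCAGCTCCGGATGGTTAAAT
8	forward	none	TCGTCGGCAGCGTCAGATGTGTATAAGAGACAG	TTTCAAAAGCTTTGCGTGAG
8	reverse	none	GTCTCGTGGGCTCGGAGATGTGTATAAGAGACAG	GATGCTTCACGTTCACACCA
8	forward	T	TCGTCGGCAGCGTCAGATGTGTATAAGAGACAG	TTTCAAAAGCTTTGCGTGAG
8	reverse	T	GTCTCGTGGGCTCGGAGATGTGTATAAGAGACAG	GATGCTTCACGTTCACACCA
9	forward	none	TCGTCGGCAGCGTCAGATGTGTATAAGAGACAG	GTTCTATCCAAGGGCCATCA
9	reverse	none	GTCTCGTGGGCTCGGAGATGTGTATAAGAGACAG	CCCATGGAAACTCCTTGTTG
9	forward	A	TCGTCGGCAGCGTCAGATGTGTATAAGAGACAG	GTTCTATCCAAGGGCCATCA
9	reverse	A	GTCTCGTGGGCTCGGAGATGTGTATAAGAGACAG	CCCATGGAAACTCCTTGTTG
10	forward	none	TCGTCGGCAGCGTCAGATGTGTATAAGAGACAG	GATCCGTCGGCTCTTCTCTC
10	reverse	none	GTCTCGTGGGCTCGGAGATGTGTATAAGAGACAG	AACCATGCCAATGCTTCATA
11	forward	none	TCGTCGGCAGCGTCAGATGTGTATAAGAGACAG	GGAGCAAGTCCCAAACAAAG
11	reverse	none	GTCTCGTGGGCTCGGAGATGTGTATAAGAGACAG	CATTTCAAGCCGCTCTGG
11	forward	T	TCGTCGGCAGCGTCAGATGTGTATAAGAGACAG	GGAGCAAGTCCCAAACAAAG
11	reverse	T	GTCTCGTGGGCTCGGAGATGTGTATAAGAGACAG	CATTTCAAGCCGCTCTGG
12	forward	none	TCGTCGGCAGCGTCAGATGTGTATAAGAGACAG	TGCATTCGATCTCGATCTTG
12	reverse	none	GTCTCGTGGGCTCGGAGATGTGTATAAGAGACAG	CGGTGGTGAAGACAACAATC
12	forward	A	TCGTCGGCAGCGTCAGATGTGTATAAGAGACAG	TGCATTCGATCTCGATCTTG
12	reverse	A	GTCTCGTGGGCTCGGAGATGTGTATAAGAGACAG	CGGTGGTGAAGACAACAATC
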