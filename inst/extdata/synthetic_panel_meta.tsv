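marker_id	repeat_unit	wt_length	left_flank	right_flank
M01	T	7	TTGGATCTTA	CGGCTAGGTT
M02	C	8	ATTGACAAAG	AAATAGCGCA
M03	C	9	AGAACTAGAT	GCGGACGTGC
M04	T	10	ACCAGTATCA	ACACTCTGAC
M05	A	11	TACTTCATAG	TCCACGTTGA
M06	C	12	GCGCGTACAA	TTTGGATCCA
M07	A	7	CCTGGATGTC	TAATCGTGAA
M08	T	8	TGGGATTGCA	GTCCTCTGAA
M09	T	9	GCGAAGCTCC	GGTCACGTCG
M10	C	10	CAGCCGGACA	TGATTTGTGG
M11	A	11	CGAACATACT	GTCTATGCCT
M12	C	12	TATTCTGACG	GTTCGAATTT
M13	G	7	CACAGAACAT	CAACTGCAAC
M14	T	8	TTCAAGGAGA	GTATACTCAA
M15	G	9	TGTATATCTT	AGCCTGGTAT
M16	T	10	TGAAACAATG	CTGGATCCAG
M17	T	11	TAACACTCAG	GGACCATTGA
M18	T	12	GATAATCGGA	CGGCGACCGG
M19	T	7	TAGATCAAGA	CTTGCAGTTA
M20	T	8	AAGTCTTAGG	ACCTGAGCGA
M21	C	9	TGTCCGGACG	GGGTATCTCG
M22	A	10	TAGGCTCAGT	GCAAGAATGT
M23	A	11	GGAGCGCGTC	TGGAGGTGCA
M24	A	12	GTGTCGTGAT	TACAGAGCGC
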