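assay,gene,orientation,sequence,expected_size,annealing_c,diagnostic_allele
P1,TaPod-D1,forward,AGCACACAAGGAGAGAGGAG,488,64,
P1,TaPod-D1,reverse,AAGAGGCACGCGGTAGTCG,488,64,
P2,TaPod-D1,forward,CGACTACCGCGTGCCTCTT,655,62,
P2,TaPod-D1,reverse,TAGTCCACTTGTCTAGATGCTT,655,62,
P3,TaPod-A2,forward,GCTACCCTTGAATCCTGCCTA,752,64,
P3,TaPod-A2,reverse,CTCGAAGGAGGAGCAGTGC,752,64,
P4,TaPod-A2,forward,GGACTACCGCGTGCCTCTC,629,64,
P4,TaPod-A2,reverse,GCTAGCCAAGGCTTTCTTCG,629,64,
P5,TaPod-A3,forward,CCTCGTCAGCGGGGTTCG,574,62,
P5,TaPod-A3,reverse,CCGTGCATTCGCATTCAAG,574,62,
P6,TaPod-B1,forward,GCCTCGTCAGCGGGTTCC,580,62,
P6,TaPod-B1,reverse,CGTGCCAACACAACACACTG,580,62,
POD-7D6,TaPod-D1,forward,TGGGCATGGGGCTTCTGCA,640,58,TaPod-D1a
POD-7D6,TaPod-D1,reverse,GCGAGGAATGGGGGGTTGATG,640,58,TaPod-D1a
POD-7D1,TaPod-D1,forward,GCTTCGTCCAGGACGCCGTT,540,61,TaPod-D1b
POD-7D1,TaPod-D1,reverse,CGAGGAATGGGGGGTTGATG,540,61,TaPod-D1b
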