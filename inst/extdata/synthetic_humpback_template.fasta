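>synthetic_humpback_template printed oligo footprints at printed offsets; inter-oligo infill is synthetic
ACACGTGGTTCCGGAACTACACCCTCGATGGCCGCTCCATTAGATCACGAGTACTCGACTAAATATTATC
GGCTTCACTGGTTCCGCCACCTCGCTGCATGCGGATCGCACCGGGCCCATCAATCGTCGTTGTACGCTGG
ACCAAGGTAAATCCATCAGACTGGTTCTTACTTCAGGGCCAGCGATTAAGGAACGTTTACAGGACAACTA
G
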