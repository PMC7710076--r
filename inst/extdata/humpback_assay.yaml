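name: humpback
forward:
  name: 287F
  sequence: GCCGCTCCATTAGATCACGA
  concentration_uM: 0.2
reverse:
  name: 437R
  sequence: TGGCCCTGAAGTAAGAACCAG
  concentration_uM: 0.2
probe:
  name: 362P
  sequence: TCGCACCGGGCCCATCAATCGT
  concentration_uM: 0.1
  reporter: FAM
  quencher: BHQ
ta_C: 60
cq_threshold: 0.01
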