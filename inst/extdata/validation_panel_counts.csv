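# Tissue-panel validation outcomes per assay (in-vitro testing).
assay,total_target,tp,fn,total_nontarget,tn,fp
humpback,4,4,0,26,21,5
rockfish,3,3,0,37,29,8
murre,3,3,0,9,9,0
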