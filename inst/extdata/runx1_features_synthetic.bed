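chr21	36560000	36572000	distal_promoter
chr21	36540000	36541200	exon_1
chr21	36480000	36481100	exon_2
chr21	36390000	36391000	exon_3
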