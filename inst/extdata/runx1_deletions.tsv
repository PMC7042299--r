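label	chrom	start	end	set
FML029	chr21	36349450	36572837	array
FML030	chr21	36400658	36972948	array
FML031	chr21	36389492	37056053	array
FML031	chr21	36389457	37055677	report
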