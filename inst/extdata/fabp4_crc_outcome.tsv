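snp	chr	pos	effect_allele	other_allele	eaf	beta	se	pval	n
rs2012444	3	12375956	T	C	0.12	-0.01	0.01	NA	125478
rs77878271	8	82395535	A	G	0.98	0.05	0.03	NA	125478
rs79389622	9	126081452	A	G	0.00	-0.07	0.08	NA	125478
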