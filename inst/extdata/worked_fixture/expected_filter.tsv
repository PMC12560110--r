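contig_id	kept	reasons
f_keep	TRUE	
f_len300	TRUE	
f_len299	FALSE	LEN
f_gc42	TRUE	
f_gc43	FALSE	GC
f_tax_host	FALSE	TAX
f_tax_none	FALSE	TAX
f_cov5	TRUE	
f_cov4	FALSE	COV
f_len_gc	FALSE	LEN,GC
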