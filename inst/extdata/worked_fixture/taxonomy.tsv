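f_keep	Cardinium
f_len300	Cardinium
f_len299	Cardinium
f_gc42	Cardinium
f_gc43	Cardinium
f_tax_host	host
f_cov5	Cardinium
f_cov4	Cardinium
f_len_gc	Cardinium
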