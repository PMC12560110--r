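contig_id	evaluated	flagged	traits_met
p_plasmid	TRUE	TRUE	GC,PAR,CONTENT
p_chrom	TRUE	FALSE	
p_small	FALSE	FALSE	
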