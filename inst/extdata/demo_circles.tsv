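chrom	start	end	copies	cell_fraction
chr1	2000000	2005000	4	1
chr2	250000	280000	3	1
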