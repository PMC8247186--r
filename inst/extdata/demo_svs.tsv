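svtype	chrom	start	end	svlen	chrom2	pos2	cell_fraction
DEL	chr1	500000	503000	-3000	NA	NA	1
INS	chr1	1200000	1200001	800	NA	NA	1
DUP	chr2	700000	704000	4000	NA	NA	1
INV	chr2	1500000	1520000	20000	NA	NA	1
TRA	chr1	2500000	2500001	0	chr2	2600000	1
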