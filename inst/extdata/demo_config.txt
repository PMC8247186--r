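# Demo simulation: 6 cells over a 6 Mb toy genome with planted variants.
# Paths to the planted-variant tables are resolved relative to the working
# directory; the packaged copies live next to this file.
seed: 42
n_cells: 6
chrom_lengths: chr1=3000000,chr2=3000000
per_cell_coverage: 0.4
mean_fragment_bp: 6000
fp_sv_per_cell: 5
imprecise_frac: 0.1
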