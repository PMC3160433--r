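# Per-classification gene-tree counts from a published clanistic survey of
# the E. coli pangenome. "wild" = forest seeded from one uropathogenic
# strain against all relatives; "pangenome" = forest over all strains.
# natives: the category treated as native (ecoli, mge, path). The three
# mge_containing_* rows are the published counts of MGE-containing trees by
# grouping class; forest_total rows give the forest sizes used for
# percentages.
forest	natives	classification	n
wild	ecoli	pure	140
wild	ecoli	perfect_clan	308
wild	ecoli	perfect_slice	343
wild	ecoli	melange	3174
wild	ecoli	forest_total	4065
wild	mge	mge_containing_a	302
wild	mge	mge_containing_b	52
wild	mge	mge_containing_c	66
wild	mge	forest_total	4065
pangenome	mge	mge_containing_a	474
pangenome	mge	mge_containing_b	184
pangenome	mge	mge_containing_c	174
pangenome	mge	forest_total	6129
pangenome	path	pure	546
pangenome	path	perfect_clan	735
pangenome	path	perfect_slice	547
pangenome	path	melange	4291
pangenome	path	forest_total	6129
pangenome	ecoli	melange	176
pangenome	ecoli	perfect_slice	186
pangenome	ecoli	forest_total	6129
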