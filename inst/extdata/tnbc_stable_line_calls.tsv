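# Subtype calls for the six molecularly stable TNBC cell lines re-derived
# from five independent expression sources: three public cell-line
# compendia (GSE15361, GSE10890, CCLE), xenograft tumor RNA-seq, and the
# original 2188-gene cell-line classification. A cell line absent from a
# source simply has no row for that condition (the condition is skipped
# when assessing stability).
sample_id	condition	status	primary_subtype	primary_rho	dual_subtypes	im_status
HCC70	gse15361	single	BL2	0.22		undetermined
HCC70	gse10890	single	BL2	0.26		undetermined
HCC70	ccle	single	BL2	0.27		undetermined
HCC70	xenograft	single	BL2	0.38		undetermined
HCC70	lehmann2011	single	BL2	0.24		undetermined
SUM149PT	gse15361	single	BL2	0.14		undetermined
SUM149PT	ccle	single	BL2	0.21		undetermined
SUM149PT	xenograft	single	BL2	0.37		undetermined
SUM149PT	lehmann2011	single	BL2	0.30		undetermined
HCC1806	gse10890	single	BL2	0.42		undetermined
HCC1806	ccle	single	BL2	0.26		undetermined
HCC1806	xenograft	single	BL2	0.49		undetermined
HCC1806	lehmann2011	single	BL2	0.22		undetermined
BT549	gse15361	single	M	0.18		undetermined
BT549	gse10890	single	M	0.11		undetermined
BT549	ccle	single	M	0.15		undetermined
BT549	xenograft	single	M	0.41		undetermined
BT549	lehmann2011	single	M	0.21		undetermined
MDAMB453	gse15361	single	LAR	0.30		undetermined
MDAMB453	gse10890	single	LAR	0.48		undetermined
MDAMB453	ccle	single	LAR	0.40		undetermined
MDAMB453	xenograft	single	LAR	0.38		undetermined
MDAMB453	lehmann2011	single	LAR	0.53		undetermined
HCC2157	gse15361	single	BL1	0.44		undetermined
HCC2157	ccle	single	BL1	0.40		undetermined
HCC2157	xenograft	single	BL1	0.33		undetermined
HCC2157	lehmann2011	single	BL1	0.66		undetermined
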