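# Subtype calls for 17 TNBC cell lines profiled in vitro and as xenograft
# tumors, as reported under two centroid classifiers: the 2188-gene
# algorithm (TNBCtype) and the 101-gene algorithm (TNBCtype-IM).
# primary_rho is the published Spearman correlation of the winning subtype;
# dual_subtypes lists reported secondary subtypes as name:rho, ranked by
# correlation. IM status was not reported per call and is left undetermined.
sample_id	condition	status	primary_subtype	primary_rho	dual_subtypes	im_status
HCC70	tnbctype_invitro	single	BL2	0.24		undetermined
HCC70	tnbctypeim_invitro	dual	BL2	0.27	BL1:0.25	undetermined
HCC70	tnbctype_xeno	single	BL2	0.36		undetermined
HCC70	tnbctypeim_xeno	single	BL2	0.38		undetermined
SUM149PT	tnbctype_invitro	single	BL2	0.3		undetermined
SUM149PT	tnbctypeim_invitro	dual	BL2	0.21	M:0.17	undetermined
SUM149PT	tnbctype_xeno	single	BL2	0.40		undetermined
SUM149PT	tnbctypeim_xeno	single	BL2	0.37		undetermined
HCC1806	tnbctype_invitro	single	BL2	0.22		undetermined
HCC1806	tnbctypeim_invitro	single	BL2	0.26		undetermined
HCC1806	tnbctype_xeno	single	BL2	0.42		undetermined
HCC1806	tnbctypeim_xeno	single	BL2	0.49		undetermined
BT549	tnbctype_invitro	single	M	0.21		undetermined
BT549	tnbctypeim_invitro	single	M	0.15		undetermined
BT549	tnbctype_xeno	single	M	0.40		undetermined
BT549	tnbctypeim_xeno	single	M	0.41		undetermined
MDAMB453	tnbctype_invitro	single	LAR	0.53		undetermined
MDAMB453	tnbctypeim_invitro	single	LAR	0.4		undetermined
MDAMB453	tnbctype_xeno	single	LAR	0.37		undetermined
MDAMB453	tnbctypeim_xeno	single	LAR	0.38		undetermined
HCC2157	tnbctype_invitro	single	BL1	0.66		undetermined
HCC2157	tnbctypeim_invitro	single	BL1	0.4		undetermined
HCC2157	tnbctype_xeno	single	BL1	0.68		undetermined
HCC2157	tnbctypeim_xeno	single	BL1	0.33		undetermined
SUM185PE	tnbctype_invitro	single	LAR	0.39		undetermined
SUM185PE	tnbctypeim_invitro	unstable	UNS			undetermined
SUM185PE	tnbctype_xeno	unstable	UNS			undetermined
SUM185PE	tnbctypeim_xeno	single	LAR	0.32		undetermined
BT20	tnbctype_invitro	unstable	UNS			undetermined
BT20	tnbctypeim_invitro	single	BL2	0.18		undetermined
BT20	tnbctype_xeno	single	LAR	0.36		undetermined
BT20	tnbctypeim_xeno	single	LAR	0.32		undetermined
MDAMB157	tnbctype_invitro	single	MSL	0.25		undetermined
MDAMB157	tnbctypeim_invitro	single	LAR	0.12		undetermined
MDAMB157	tnbctype_xeno	single	BL2	0.21		undetermined
MDAMB157	tnbctypeim_xeno	single	LAR	0.17		undetermined
SUM159PT	tnbctype_invitro	single	MSL	0.14		undetermined
SUM159PT	tnbctypeim_invitro	dual	BL2	0.18	LAR:0.16	undetermined
SUM159PT	tnbctype_xeno	single	BL2	0.47		undetermined
SUM159PT	tnbctypeim_xeno	single	BL2	0.54		undetermined
MDAMB468	tnbctype_invitro	single	BL1	0.19		undetermined
MDAMB468	tnbctypeim_invitro	dual	BL2	0.2	BL1:0.13	undetermined
MDAMB468	tnbctype_xeno	unstable	UNS			undetermined
MDAMB468	tnbctypeim_xeno	dual	BL2	0.24	M:0.23	undetermined
MDAMB231	tnbctype_invitro	single	MSL	0.12		undetermined
MDAMB231	tnbctypeim_invitro	single	BL2	0.24		undetermined
MDAMB231	tnbctype_xeno	unstable	UNS			undetermined
MDAMB231	tnbctypeim_xeno	single	BL2	0.25		undetermined
HCC1187	tnbctype_invitro	single	IM	0.22		undetermined
HCC1187	tnbctypeim_invitro	single	BL2	0.17		undetermined
HCC1187	tnbctype_xeno	single	BL2	0.32		undetermined
HCC1187	tnbctypeim_xeno	dual	BL2	0.17	BL1:0.14	undetermined
DU4475	tnbctype_invitro	single	IM	0.17		undetermined
DU4475	tnbctypeim_invitro	single	BL1	0.14		undetermined
DU4475	tnbctype_xeno	unstable	UNS			undetermined
DU4475	tnbctypeim_xeno	unstable	UNS			undetermined
MDAMB436	tnbctype_invitro	single	MSL	0.13		undetermined
MDAMB436	tnbctypeim_invitro	unstable	UNS			undetermined
MDAMB436	tnbctype_xeno	single	LAR	0.33		undetermined
MDAMB436	tnbctypeim_xeno	single	LAR	0.39		undetermined
HCC1937	tnbctype_invitro	single	BL1	0.28		undetermined
HCC1937	tnbctypeim_invitro	single	BL2	0.37		undetermined
HCC1937	tnbctype_xeno	single	BL1	0.37		undetermined
HCC1937	tnbctypeim_xeno	dual	BL2	0.34	M:0.19	undetermined
HCC3153	tnbctype_invitro	single	BL1	0.24		undetermined
HCC3153	tnbctypeim_invitro	single	BL1	0.37		undetermined
HCC3153	tnbctype_xeno	unstable	UNS			undetermined
HCC3153	tnbctypeim_xeno	single	M	0.45		undetermined
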