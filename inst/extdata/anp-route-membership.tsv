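# Vessel-level membership map for the raw route: span is a single
# identifier or a first..last range resolved against the raw path order.
# label is the condensed group; sublabel (optional) refines a group into
# sub-vessel runs (here: the chamber portion of the right atrium vs the
# right ventricle inside the heart group).
span	label	sublabel
TF-7096	TF_right_atrium
BND-12078	ENS_right_atrium_capillaries
CAP-CVS-448	capillaries_right_atrium
VNL-CVS-448	venules_right_atrium
CVS-2076	right_marginal_vein
CVS-2075	anterior_cardiac_vein
CVS-2074..CVS-1333	right_heart	RA_chamber
RV	right_heart	right_ventricle
PC	pulmonary_circulation
LH	left_heart
CVS-2407..CVS-5870	aorta
CVS-5871	left_accessory_renal_artery
ARTL-CVS-25	arterioles_left_kidney
BND-12524	ENS_left_kidney
TF-ARTL-CVS-25	TF_left_kidney
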