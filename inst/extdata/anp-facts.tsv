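# Minimal ground facts defining the demonstration hormone/receptor pair:
# a secreted natriuretic peptide found post-production in the right-atrium
# tissue fluid, and its receptor in the smooth muscle of the left-kidney
# arterioles. Site kinds are declared so subcellular location types can be
# inferred.
!ind	TF-7096	TissueFluid	.	.	Tissue fluid of the right atrium
!ind	SM-ARTL-CVS-25	TissueStructure	.	.	Smooth muscle of the left-kidney arterioles
Protein	anp
fnd-in-postp	anp	TF-7096
Protein	anpr
fnd-in-postp	anpr	SM-ARTL-CVS-25
CMTP_t	anp	adv
CMTP_t	anp	dif
CMTP_t	anp	cnv
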