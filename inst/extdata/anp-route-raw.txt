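# Raw elicited route, one compartment identifier per line, in route order:
# from the tissue fluid of the right atrium to the tissue fluid of the
# left-kidney arterioles.
TF-7096
BND-12078
CAP-CVS-448
VNL-CVS-448
CVS-2076
CVS-2075
CVS-2074
CVS-2072
CVS-1333
RV
PC
LH
CVS-2407
CVS-2573
CVS-2657
CVS-3780
CVS-4288
CVS-4707
CVS-4709
CVS-4711
CVS-4713
CVS-4715
CVS-4716
CVS-4650
CVS-4719
CVS-4770
CVS-4819
CVS-4868
CVS-4917
CVS-4964
CVS-5011
CVS-5058
CVS-5105
CVS-5152
CVS-5199
CVS-5246
CVS-5293
CVS-5295
CVS-5297
CVS-5344
CVS-5391
CVS-5438
CVS-5485
CVS-5532
CVS-5579
CVS-5618
CVS-5657
CVS-5659
CVS-5661
CVS-5673
CVS-5685
CVS-5812
CVS-5864
CVS-5866
CVS-5868
CVS-5870
CVS-5871
ARTL-CVS-25
BND-12524
TF-ARTL-CVS-25
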