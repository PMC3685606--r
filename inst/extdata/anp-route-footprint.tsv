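# Modality footprint of the condensed reference route: maximal runs of one
# transport modality over the condensed group indices.
modality	from	to
Diffusion	1	1
Convection	2	2
Advection	3	12
Convection	13	13
Diffusion	14	14
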