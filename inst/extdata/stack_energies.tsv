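# Nearest-neighbour stack free energies (kcal/mol), simplified Turner-style set, v1.
# Motif XY/ZW denotes the stacked 2x2: 5'-X Y-3' over 3'-Z W-5', with X:Z and Y:W paired.
# Lookup applies the rotational symmetry XY/ZW == WZ/YX; only one representative per motif is listed.
# Watson-Crick stacks follow the Turner 2004 values; G:U-containing stacks are a reduced
# Turner 1999-style set. Helix initiation (one charge per helix, at its innermost pair)
# is listed as motif INIT.
motif	dG
AA/UU	-0.93
AU/UA	-1.10
UA/AU	-1.33
CU/GA	-2.08
CA/GU	-2.11
GU/CA	-2.24
GA/CU	-2.35
CG/GC	-2.36
GG/CC	-3.26
GC/CG	-3.42
AG/UU	-0.55
AU/UG	-1.36
CG/GU	-1.41
CU/GG	-2.11
GG/CU	-1.53
GU/CG	-2.51
UG/AU	-1.27
UU/AG	-1.00
GG/UU	-0.50
GU/UG	0.50
UG/GU	-0.60
INIT	4.10
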