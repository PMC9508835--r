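# Reduced nearest-neighbor helix stacking free energies, kcal/mol at 37 C.
# Row key: outer (5') pair XY then inner (3') pair; stack of pair (i,j) on (i+1,j-1).
# Watson-Crick and GU wobble pairs only. SHAPE pseudo-free-energy terms
# (m*ln(S+1)+b) are added once per stack for each of the four nucleotides in
# the stack, so helix-internal nucleotides accrue the term twice and helix-end
# nucleotides once.
outer	inner	dg
AU	AU	-0.9
AU	UA	-1.1
AU	GC	-2.1
AU	CG	-2.2
AU	GU	-0.6
AU	UG	-1.4
UA	AU	-1.3
UA	UA	-0.9
UA	GC	-2.1
UA	CG	-2.4
UA	GU	-1.0
UA	UG	-1.3
GC	AU	-2.4
GC	UA	-2.2
GC	GC	-3.3
GC	CG	-3.4
GC	GU	-1.5
GC	UG	-2.5
CG	AU	-2.1
CG	UA	-2.1
CG	GC	-2.4
CG	CG	-3.3
CG	GU	-1.4
CG	UG	-2.1
GU	AU	-1.3
GU	UA	-1.4
GU	GC	-2.1
GU	CG	-2.5
GU	GU	-0.5
GU	UG	-0.5
UG	AU	-1.0
UG	UA	-0.6
UG	GC	-1.4
UG	CG	-1.5
UG	GU	-0.3
UG	UG	-0.5
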