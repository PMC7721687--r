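pair	x	y	dg
CG	A	A	0
CG	C	A	0
CG	G	A	-1
CG	U	A	0
CG	A	C	0
CG	C	C	0
CG	G	C	0
CG	U	C	0
CG	A	G	-0.8
CG	C	G	0
CG	G	G	-1
CG	U	G	0
CG	A	U	0
CG	C	U	0
CG	G	U	0
CG	U	U	-0.6
GC	A	A	0
GC	C	A	0
GC	G	A	-1
GC	U	A	0
GC	A	C	0
GC	C	C	0
GC	G	C	0
GC	U	C	0
GC	A	G	-0.8
GC	C	G	0
GC	G	G	-1
GC	U	G	0
GC	A	U	0
GC	C	U	0
GC	G	U	0
GC	U	U	-0.6
GU	A	A	0.7
GU	C	A	0.7
GU	G	A	-0.3
GU	U	A	0.7
GU	A	C	0.7
GU	C	C	0.7
GU	G	C	0.7
GU	U	C	0.7
GU	A	G	-0.1
GU	C	G	0.7
GU	G	G	-0.3
GU	U	G	0.7
GU	A	U	0.7
GU	C	U	0.7
GU	G	U	0.7
GU	U	U	0.1
UG	A	A	0.7
UG	C	A	0.7
UG	G	A	-0.3
UG	U	A	0.7
UG	A	C	0.7
UG	C	C	0.7
UG	G	C	0.7
UG	U	C	0.7
UG	A	G	-0.1
UG	C	G	0.7
UG	G	G	-0.3
UG	U	G	0.7
UG	A	U	0.7
UG	C	U	0.7
UG	G	U	0.7
UG	U	U	0.1
AU	A	A	0.7
AU	C	A	0.7
AU	G	A	-0.3
AU	U	A	0.7
AU	A	C	0.7
AU	C	C	0.7
AU	G	C	0.7
AU	U	C	0.7
AU	A	G	-0.1
AU	C	G	0.7
AU	G	G	-0.3
AU	U	G	0.7
AU	A	U	0.7
AU	C	U	0.7
AU	G	U	0.7
AU	U	U	0.1
UA	A	A	0.7
UA	C	A	0.7
UA	G	A	-0.3
UA	U	A	0.7
UA	A	C	0.7
UA	C	C	0.7
UA	G	C	0.7
UA	U	C	0.7
UA	A	G	-0.1
UA	C	G	0.7
UA	G	G	-0.3
UA	U	G	0.7
UA	A	U	0.7
UA	C	U	0.7
UA	G	U	0.7
UA	U	U	0.1
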