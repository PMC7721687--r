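pair	x	y	dg
CG	A	A	-1.5
CG	C	A	-1
CG	G	A	-2.3
CG	U	A	-1
CG	A	C	-1.5
CG	C	C	-1.1
CG	G	C	-1.5
CG	U	C	-1.4
CG	A	G	-1.4
CG	C	G	-1
CG	G	G	-2.4
CG	U	G	-1
CG	A	U	-1.5
CG	C	U	-0.8
CG	G	U	-1.5
CG	U	U	-2.1
GC	A	A	-1.1
GC	C	A	-1.1
GC	G	A	-2.5
GC	U	A	-1.1
GC	A	C	-1.5
GC	C	C	-0.7
GC	G	C	-1.5
GC	U	C	-1
GC	A	G	-1.3
GC	C	G	-1.1
GC	G	G	-2.2
GC	U	G	-1.1
GC	A	U	-1.5
GC	C	U	-0.5
GC	G	U	-1.5
GC	U	U	-1.6
GU	A	A	0.2
GU	C	A	-0.1
GU	G	A	-1
GU	U	A	-0.1
GU	A	C	-0.5
GU	C	C	-0.2
GU	G	C	-0.5
GU	U	C	-0.3
GU	A	G	-0.3
GU	C	G	-0.1
GU	G	G	-1.1
GU	U	G	-0.1
GU	A	U	-0.5
GU	C	U	-0.2
GU	G	U	-0.5
GU	U	U	-1
UG	A	A	-0.5
UG	C	A	-0.2
UG	G	A	-0.9
UG	U	A	-0.2
UG	A	C	-0.3
UG	C	C	-0.1
UG	G	C	-0.3
UG	U	C	-0.1
UG	A	G	-0.6
UG	C	G	-0.2
UG	G	G	-1.1
UG	U	G	-0.2
UG	A	U	-0.3
UG	C	U	0
UG	G	U	-0.3
UG	U	U	-0.9
AU	A	A	-0.3
AU	C	A	-0.1
AU	G	A	-1.2
AU	U	A	-0.1
AU	A	C	-0.5
AU	C	C	-0.2
AU	G	C	-0.5
AU	U	C	-0.3
AU	A	G	-0.3
AU	C	G	-0.1
AU	G	G	-1.1
AU	U	G	-0.1
AU	A	U	-0.5
AU	C	U	-0.2
AU	G	U	-0.5
AU	U	U	-1.2
UA	A	A	-0.5
UA	C	A	-0.2
UA	G	A	-1.5
UA	U	A	-0.2
UA	A	C	-0.3
UA	C	C	-0.1
UA	G	C	-0.3
UA	U	C	-0.1
UA	A	G	-0.5
UA	C	G	-0.2
UA	G	G	-1.5
UA	U	G	-0.2
UA	A	U	-0.3
UA	C	U	0
UA	G	U	-0.3
UA	U	U	-0.9
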