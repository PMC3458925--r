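ap	S	Q	N	T	C	G	A	H	M	Y	F	V	L	P	I	W	D	E	K	R
S	-	-	-	-	i	-	i	-	-	-	-	-	-	-	-	-	-	-	-	b
Q	-	-	-	-	-	-	i	-	-	-	-	-	i	-	-	-	-	i	-	-
N	-	-	-	-	-	i	i	-	-	-	-	-	-	-	-	-	-	-	-	i
T	-	-	-	-	-	b	b	-	-	-	-	b	b	-	-	-	-	b	-	b
C	b	-	-	-	-	-	b	-	-	-	-	b	-	-	b	-	-	-	-	b
G	-	-	b	-	-	-	b	b	-	-	-	-	-	-	-	-	-	-	-	-
A	b	b	b	i	i	-	-	b	b	-	b	-	-	i	-	b	-	-	b	-
H	-	-	-	-	-	i	i	-	-	-	-	-	b	-	-	-	-	-	-	i
M	-	-	-	-	-	-	i	-	-	-	-	b	b	-	b	-	-	-	-	b
Y	-	-	-	-	-	-	-	i	-	-	-	-	-	-	-	i	-	-	-	-
F	-	-	-	-	-	-	i	-	-	-	-	i	-	-	b	-	-	-	-	-
V	-	-	-	i	i	-	-	-	i	-	b	-	b	-	-	-	-	-	-	-
L	-	b	-	i	-	-	-	i	i	b	-	i	-	-	b	b	-	-	-	-
P	-	-	-	-	-	-	b	-	-	-	-	-	-	-	-	-	-	-	-	-
I	-	-	-	-	i	-	-	-	i	-	i	-	i	-	-	-	-	-	-	-
W	-	-	-	-	-	-	i	-	-	b	b	-	i	-	-	-	-	-	-	-
D	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-
E	-	b	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-
K	-	-	-	-	-	-	i	-	-	-	-	-	-	-	-	-	-	-	-	i
R	i	b	b	i	i	-	-	b	i	-	-	-	-	-	-	-	-	-	b	-
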