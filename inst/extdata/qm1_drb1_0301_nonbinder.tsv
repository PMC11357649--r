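# role: non-binder
aa	p1	p2	p3	p4	p5	p6	p7	p8	p9
A	-0.078	0.109	0.234	0.422	0.297	-0.141	0.047	0.359	0.422
R	-0.016	-0.078	0.047	-0.141	-0.141	-0.078	-0.016	0.109	-0.203
N	-0.078	0.109	0.047	-0.016	-0.078	-0.141	-0.141	-0.203	-0.141
D	0.172	-0.016	0.109	-0.078	-0.203	-0.078	-0.203	-0.266	-0.266
C	-0.203	0.047	-0.328	-0.016	-0.203	0.047	-0.141	-0.078	-0.016
Q	-0.141	-0.141	0.109	-0.266	-0.078	-0.203	-0.203	-0.141	-0.141
E	0.297	0.047	0.109	-0.078	-0.078	-0.203	0.047	-0.141	-0.016
G	0.047	0.359	0.359	0.172	0.109	-0.016	0.297	0.047	0.609
H	-0.141	-0.203	-0.078	-0.141	-0.203	0.109	-0.266	-0.016	-0.141
I	0.047	-0.078	-0.016	0.047	0.172	0.047	0.172	0.109	0.047
L	-0.078	0.234	-0.016	0.359	-0.016	0.359	0.484	0.422	0.422
K	0.297	0.297	-0.078	-0.078	0.109	-0.078	-0.141	0.047	-0.078
M	-0.328	-0.078	-0.078	-0.016	-0.078	-0.078	-0.203	0.047	-0.141
F	-0.078	-0.141	-0.203	-0.016	0.234	-0.141	-0.078	-0.203	0.047
P	-0.141	-0.078	-0.203	-0.141	-0.078	-0.266	0.172	-0.016	-0.266
S	0.484	0.234	0.234	0.359	0.359	0.672	0.172	0.109	0.234
T	-0.141	-0.078	0.234	-0.141	0.047	-0.141	-0.078	0.047	0.172
W	-0.328	-0.328	-0.266	-0.266	-0.203	-0.141	-0.266	-0.203	-0.266
Y	-0.078	-0.203	-0.328	-0.078	-0.016	0.172	0.047	-0.141	-0.203
V	0.484	-0.016	0.109	0.109	0.047	0.297	0.297	0.109	-0.078
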