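# role: binder
aa	p1	p2	p3	p4	p5	p6	p7	p8	p9
A	-0.083	-0.157	0.213	0.324	0.324	0.176	0.102	0.028	-0.046
R	0.028	-0.046	0.176	0.324	0.176	0.176	0.102	0.398	0.213
N	-0.194	-0.194	-0.120	-0.157	-0.009	-0.120	-0.046	-0.194	-0.194
D	-0.194	-0.194	-0.083	-0.009	-0.157	-0.194	-0.083	-0.120	-0.194
C	-0.157	-0.194	-0.194	-0.157	-0.194	-0.194	-0.194	-0.194	-0.157
Q	-0.194	-0.009	-0.046	-0.157	-0.120	-0.083	-0.157	-0.120	-0.194
E	-0.157	-0.120	-0.194	-0.120	-0.157	-0.194	-0.083	-0.120	-0.157
G	-0.120	-0.157	-0.083	0.065	-0.083	-0.083	-0.046	-0.046	-0.194
H	-0.120	-0.120	-0.009	-0.120	-0.157	-0.046	-0.009	-0.120	-0.157
I	0.213	-0.009	0.065	-0.009	0.102	-0.194	0.065	-0.009	0.139
L	0.324	0.694	0.176	0.324	-0.009	0.139	0.435	0.398	0.583
K	-0.157	-0.157	-0.083	0.065	0.176	0.139	-0.009	0.028	0.435
M	0.102	0.324	0.324	-0.046	-0.046	-0.120	-0.046	0.065	-0.083
F	0.806	-0.046	0.102	-0.009	-0.009	0.250	0.250	0.287	0.102
P	-0.157	-0.194	-0.120	-0.120	0.065	0.176	-0.009	-0.083	-0.194
S	-0.046	-0.120	0.028	0.176	0.065	0.065	-0.083	-0.083	-0.194
T	-0.194	0.028	-0.157	-0.157	-0.009	0.102	-0.046	-0.046	-0.157
W	0.102	0.102	-0.009	-0.083	-0.083	-0.083	-0.046	-0.120	-0.083
Y	0.324	0.546	0.102	-0.009	-0.009	0.028	0.028	-0.009	0.361
V	-0.120	0.028	-0.083	-0.120	0.139	0.065	-0.120	0.065	0.176
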