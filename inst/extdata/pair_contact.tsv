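atype	C_aliph	C_arom	N_don	O_acc	S	P
C_aliph	-0.4	-0.3	0	0	-0.2	0
C_arom	-0.3	-0.5	-0.1	-0.1	-0.2	0
N_don	0	-0.1	0.1	-0.6	0	-0.1
O_acc	0	-0.1	-0.6	0.1	0	-0.1
S	-0.2	-0.2	0	0	-0.3	0
P	0	0	-0.1	-0.1	0	0.1
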