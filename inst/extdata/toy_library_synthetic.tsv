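sample	D1	D2	D3	D4	D5	class
I1	L	M	H	L	M	1
I2	M	L	L	H	H	1
I3	H	L	M	H	L	1
I4	L	H	L	M	H	0
I5	M	M	H	L	L	1
I6	H	L	M	H	M	0
I7	L	H	L	M	H	0
I8	M	M	H	L	L	0
I9	L	L	M	H	H	1
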