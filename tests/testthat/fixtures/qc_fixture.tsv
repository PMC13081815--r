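barcode	g01	g02	g03	g04	g05	g06	g07	g08	g09	g10	g11	g12
c1	3	2	2	1	1	1	0	0	0	0	0	0
c2	4	2	2	1	0	0	2	1	0	0	0	0
c3	1	1	1	1	1	1	1	0	0	0	0	0
c4	5	5	0	0	0	0	0	0	0	0	0	0
c5	0	0	0	0	4	3	2	0	2	0	0	0
c6	3	3	3	0	0	0	0	0	0	0	0	0
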