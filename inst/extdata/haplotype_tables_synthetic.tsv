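group	amy1	amy2a	amy2b	frequency
Arab	1	1	1	0.14
Arab	3	1	1	0.50
Arab	5	1	1	0.165
Arab	7	1	1	0.04
Arab	9	1	1	0.02
Arab	11	1	1	0.005
Arab	2	0	1	0.05
Arab	4	2	1	0.05
Arab	6	2	2	0.03
Persian	1	1	1	0.14625
Persian	3	1	1	0.40
Persian	5	1	1	0.10875
Persian	7	1	1	0.08
Persian	9	1	1	0.04
Persian	11	1	1	0.01
Persian	2	0	1	0.04
Persian	4	2	1	0.125
Persian	6	2	2	0.05
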