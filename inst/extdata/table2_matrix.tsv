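species	char_01	char_02	char_03	char_04	char_05	char_06	char_07	char_08	char_09	char_10	char_11	char_12	char_13	char_14	char_15	char_16	char_17	char_18	char_19	char_20	char_21	char_22
O. cincta	5	3	0	2	1	2	7	7	4	4	3	1	2	3	0	3	0	1	0	0	0	0
O. colluvialis	2(9)	4(7)	1	2(3)	2	5	7(9)	8	4	3	4	1	3	3	2	4	0	4	0	2	0	1
O. eolia	5	4(7)	0	2	1	3	11	8	4	4	7(8)	0	2	4(5)	0	7	0	2	0	2	0	0
O. mesovoides	5(7)	2(5)	1	2(3)	2	4(5)	12	9	4	4	4	1	3	2	0	3	1	3(6)	1	2(3)	1	3
O. villosa	4(8)	3(6)	1	2	3	5	7	5	3(4)	6	5	0(1)	3	3	0	2	0	3	0	0	0	0
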