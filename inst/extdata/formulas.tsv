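species	formula	claw_teeth	source_section	parse_mode	note
O. mesovoides	5(7)-2(5)-1-2(3)-2-4(5)/12-9/4-4/1-3-2/0-3-1_0_3(6)-1_0_2-1_0_3	4	species description	strict
O. colluvialis	2(9)-4(7)-1-2(3)-2-5/7(9)-8/3-4/1-3-3/2-4-4-2-1	4	species description	strict
O. villosa	4(8)-3(5)-1-2-3-5/7-5/6-5(6)/0(1)-3-3/0-3-3-2-2	3(4)	species description	lenient	formula conflicts with the reference character-matrix row; the matrix is treated as authoritative
O. cincta	5-3-0-2-1b-2/7-7/4-3/1-2-3/0-3-1-0-0(2*)	4	species description	strict
O. eolia	5-4(3*)-0-2-1-3/11-8/4-7/0-2-4/0-7-2-2-0	4	species description	strict
O. flavescens	?-?-?-?-?/3-6/8-4/1-3-3/3-7(8)-3-2-0	?	literature compilation	lenient	head segment has five fields where six areas exist; compiled from earlier literature
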