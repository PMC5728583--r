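trap_code	species	count
SSD-1(0.5)	O. mesovoides	6
SSD-1	O. mesovoides	20
SSD-2(0.5)	O. mesovoides	114
SSD-2	O. mesovoides	468
SSD-3(0.5)	O. mesovoides	0
SSD-3	O. mesovoides	29
SSD-4(0.5)	O. mesovoides	0
SSD-4	O. mesovoides	8
SSD-11	O. mesovoides	123
SSD-5	O. mesovoides	2
SSD-6	O. mesovoides	0
SSD-7	O. mesovoides	116
SSD-8	O. mesovoides	4
SSD-9	O. mesovoides	50
SSD-10	O. mesovoides	0
SSD-16	O. mesovoides	100
SSD-17	O. mesovoides	20
SSD-18	O. mesovoides	3
SSD-19	O. mesovoides	0
SSD-20	O. mesovoides	0
SSD-21	O. mesovoides	120
SSD-22	O. mesovoides	206
SSD-23	O. mesovoides	0
SSD-24	O. mesovoides	0
SSD-25	O. mesovoides	35
TSP-1	O. mesovoides	12
TSP-2	O. mesovoides	1
SSD-12	O. mesovoides	184
SSD-13	O. mesovoides	2
SSD-14	O. mesovoides	0
SSD-15	O. mesovoides	6
SSD-26	O. mesovoides	1
SSD-27	O. mesovoides	0
SSD-28	O. mesovoides	0
SSD-29	O. mesovoides	4
SSD-30	O. mesovoides	252
SSD-31	O. mesovoides	20
SSD-32	O. mesovoides	0
SSD-33	O. mesovoides	50
SSD-1(0.5)	O. colluvialis	260
SSD-1	O. colluvialis	207
SSD-2(0.5)	O. colluvialis	17
SSD-2	O. colluvialis	170
SSD-3(0.5)	O. colluvialis	425
SSD-3	O. colluvialis	0
SSD-4(0.5)	O. colluvialis	0
SSD-4	O. colluvialis	279
SSD-11	O. colluvialis	117
SSD-5	O. colluvialis	96
SSD-6	O. colluvialis	389
SSD-7	O. colluvialis	216
SSD-8	O. colluvialis	168
SSD-9	O. colluvialis	163
SSD-10	O. colluvialis	10
SSD-16	O. colluvialis	201
SSD-17	O. colluvialis	132
SSD-18	O. colluvialis	75
SSD-19	O. colluvialis	55
SSD-20	O. colluvialis	57
SSD-21	O. colluvialis	0
SSD-22	O. colluvialis	184
SSD-23	O. colluvialis	0
SSD-24	O. colluvialis	0
SSD-25	O. colluvialis	173
TSP-1	O. colluvialis	0
TSP-2	O. colluvialis	0
SSD-12	O. colluvialis	115
SSD-13	O. colluvialis	443
SSD-14	O. colluvialis	40
SSD-15	O. colluvialis	68
SSD-26	O. colluvialis	591
SSD-27	O. colluvialis	112
SSD-28	O. colluvialis	38
SSD-29	O. colluvialis	135
SSD-30	O. colluvialis	73
SSD-31	O. colluvialis	700
SSD-32	O. colluvialis	0
SSD-33	O. colluvialis	220
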