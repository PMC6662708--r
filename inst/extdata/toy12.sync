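TRXA	10	A	3:0:2:0:0:0	3:0:2:0:0:0	3:0:2:0:0:0	3:0:2:0:0:0	3:0:2:0:0:0	3:0:2:0:0:0	4:0:1:0:0:0	4:0:1:0:0:0	4:0:1:0:0:0
TRXA	90	A	22:0:8:0:0:0	21:0:9:0:0:0	20:0:10:0:0:0	20:0:10:0:0:0	20:0:10:0:0:0	20:0:10:0:0:0	19:0:11:0:0:0	19:0:11:0:0:0	19:0:11:0:0:0
TRXB	5	A	20:0:4:1:0:0	20:0:5:0:0:0	20:0:6:0:0:0	20:0:5:0:0:0	20:0:4:0:0:0	20:0:6:0:0:0	20:0:5:0:0:0	20:0:5:0:0:0	20:0:5:0:0:0
TRXB	50	A	11:4:0:0:0:0	10:5:0:0:0:0	9:6:0:0:0:0	10:5:0:0:0:0	11:4:0:0:0:0	9:6:0:0:0:0	10:5:0:0:0:0	10:5:0:0:0:0	10:5:0:0:0:0
TRXC	7	A	2:0:2:0:0:0	10:0:5:0:0:0	10:0:5:0:0:0	10:0:5:0:0:0	10:0:5:0:0:0	10:0:5:0:0:0	10:0:5:0:0:0	10:0:5:0:0:0	10:0:5:0:0:0
TRXD	3	A	8:0:2:0:0:0	8:0:2:0:0:0	8:0:2:0:0:0	8:0:2:0:0:0	8:0:2:0:0:0	9:0:1:0:0:0	9:0:1:0:0:0	9:0:1:0:0:0	9:0:1:0:0:0
TRXE	12	A	30:0:0:0:0:0	30:0:0:0:0:0	30:0:0:0:0:0	30:0:0:0:0:0	30:0:0:0:0:0	30:0:0:0:0:0	30:0:0:0:0:0	30:0:0:0:0:0	30:0:0:0:0:0
TRXF	8	A	10:0:5:0:0:0	10:0:5:0:0:0	10:0:5:0:0:0	10:0:5:0:0:0	10:0:5:0:0:0	10:0:5:0:0:0	10:0:5:0:0:0	10:0:5:0:0:0	0:0:0:0:0:0
TRXG	4	A	9:0:1:0:0:0	9:0:1:0:0:0	9:0:1:0:0:0	9:0:1:0:0:0	9:0:1:0:0:0	10:0:0:0:0:0	10:0:0:0:0:0	10:0:0:0:0:0	10:0:0:0:0:0
TRXH	6	A	2:0:1:0:0:0	2:0:1:0:0:0	2:0:1:0:0:0	2:0:1:0:0:0	2:0:1:0:0:0	2:0:1:0:0:0	2:0:1:0:0:0	2:0:1:0:0:0	2:0:1:0:0:0
TRXI	9	A	9:0:1:0:0:0	9:0:1:0:0:0	9:0:1:0:0:0	9:0:1:0:0:0	9:0:1:0:0:0	10:0:0:0:0:0	10:0:0:0:0:0	10:0:0:0:0:0	10:0:0:0:0:0
TRXJ	2	A	2:0:2:0:9:3	2:0:2:0:9:3	2:0:2:0:9:3	2:0:2:0:9:3	2:0:2:0:9:3	2:0:2:0:9:3	2:0:2:0:9:3	2:0:2:0:9:3	2:0:2:0:9:3
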