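chr2	3005296	3057952	LINC01250
chr15	22374999	22383000	GOLGA6L22
chr15	22394999	22403000	GOLGA8EP
chr15	22414999	22423000	HERC2P2
chr15	22434999	22443000	HERC2P7
chr15	22454999	22463000	RN7SL545P
chr15	22474999	22483000	SPATA31E3P
chr21	16454999	16457000	MIR125B2
chr21	16494999	16497000	MIR99A
chr21	16534999	16537000	MIRLET7C
chr21	16574999	16577000	MIR99AHG
chr14	105954999	105959000	ADAM6
chr14	105963999	105968000	IGHV1-2
chr14	105972999	105977000	IGHVIII-2-1
chr14	105981999	105986000	IGHV1-3
chr14	105990999	105995000	IGHV4-4
chr14	105999999	106004000	IGHV7-4-1
chr14	106008999	106013000	IGHV2-5
chr14	106017999	106022000	IGHVIII-5-1
chr14	106026999	106031000	IGHVIII-5-2
chr14	106035999	106040000	IGHV3-6
chr14	106044999	106049000	IGHV3-7
chr14	106053999	106058000	IGHV3-64D
chr14	106062999	106067000	IGHV5-10-1
chr14	106071999	106076000	IGHV3-11
chr14	106080999	106085000	IGHVIII-11-1
chr14	106089999	106094000	IGHV1-12
chr14	106098999	106103000	IGHV3-13
chr14	106107999	106112000	IGHVIII-13-1
chr14	106116999	106121000	IGHV1-14
chr14	106125999	106130000	IGHV3-15
chr14	106134999	106139000	IGHVII-15-1
chr14	106143999	106148000	IGHV3-16
chr14	106152999	106157000	IGHVIII-16-1
chr14	106161999	106166000	IGHV1-17
chr14	106170999	106175000	IGHV1-18
chr14	106179999	106184000	IGHV3-19
chr14	106188999	106193000	SLC20A1P2
chr19	54185999	54192000	CDC42EP5
chr19	54202999	54209000	LAIR1
chr19	54219999	54226000	LAIR2
chr19	54236999	54243000	LENG8
chr19	54253999	54260000	LENG8-AS1
chr19	54270999	54277000	LENG9
chr19	54287999	54294000	LILRA4
chr19	54304999	54311000	LILRA5
chr19	54321999	54328000	LILRA6
chr19	54338999	54345000	LILRB2
chr19	54355999	54362000	LILRB3
chr19	54372999	54379000	LILRB5
chr19	54389999	54396000	MBOAT7
chr19	54406999	54413000	MIR4752
chr19	54423999	54430000	RNU6-1307P
chr19	54440999	54447000	RPS9
chr19	54457999	54464000	TSEN34
chr19	54474999	54481000	TTYH1
chr19	54491999	54498000	VN1R104P
chr19	54529999	54536000	KIR3DX1
chr19	54537899	54538000	EPS8L1
chr19	54538069	54538170	FCAR
chr19	54538239	54538340	GP6
chr19	54538409	54538510	GP6-AS1
chr19	54538579	54538680	KIR2DL1
chr19	54538749	54538850	KIR2DL3
chr19	54538919	54539020	KIR2DL4
chr19	54539089	54539190	KIR2DP1
chr19	55088999	55089100	KIR2DS4
chr19	55089599	55089700	KIR3DL1
chr19	55090199	55090300	KIR3DL2
chr19	55090799	55090900	KIR3DL3
chr19	55091399	55091500	KIR3DP1
chr19	55091999	55092100	LILRA1
chr19	55092599	55092700	LILRA2
chr19	54544999	54554000	LILRB1
chr19	54579999	54589000	LILRB1-AS1
chr19	54614999	54624000	LILRB4
chr19	54649999	54659000	LILRP1
chr19	54684999	54694000	LILRP1
chr19	54719999	54729000	LILRP2
chr19	54754999	54764000	MIR8061
chr19	54789999	54799000	NCR1
chr19	54824999	54834000	NLRP2
chr19	54859999	54869000	NLRP7
chr19	54894999	54904000	PPP1R12C
chr19	54929999	54939000	RDH13
chr19	54964999	54974000	RNU6-222P
chr19	54999999	55009000	VN1R105P
chr13	111699999	111750000	LINC00354
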