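homoeolog_id	gene_name	subgenome	chromosome	arm	start_bp	end_bp	group_label
TaPP2C119	tri01	A	4A	S	1010000	1013000	.
TaPP2C137	tri01	B	4B	L	1020000	1023000	.
TaPP2C149	tri01	D	4D	L	1030000	1033000	.
TaPP2C121	tri02	A	4A	S	2010000	2013000	.
TaPP2C135	tri02	B	4B	L	2020000	2023000	.
TaPP2C147	tri02	D	4D	L	2030000	2033000	.
TaPP2C122	tri03	A	4A	S	3010000	3013000	.
TaPP2C134	tri03	B	4B	L	3020000	3023000	.
TaPP2C146	tri03	D	4D	L	3030000	3033000	.
TaPP2C123	tri04	A	4A	S	4010000	4013000	.
TaPP2C133	tri04	B	4B	L	4020000	4023000	.
TaPP2C145	tri04	D	4D	L	4030000	4033000	.
TaPP2C124	tri05	A	4A	S	5010000	5013000	.
TaPP2C132	tri05	B	4B	L	5020000	5023000	.
TaPP2C144	tri05	D	4D	L	5030000	5033000	.
TaPP2C126	tri06	A	4A	L	6010000	6013000	.
TaPP2C130	tri06	B	4B	S	6020000	6023000	.
TaPP2C141	tri06	D	4D	S	6030000	6033000	.
TaPP2C163	tri07	A	5A	L	7010000	7013000	.
TaPP2C138	tri07	B	4B	L	7020000	7023000	.
TaPP2C150	tri07	D	4D	L	7030000	7033000	.
TaPP2C164	tri08	A	5A	L	8010000	8013000	.
TaPP2C139	tri08	B	4B	L	8020000	8023000	.
TaPP2C151	tri08	D	4D	L	8030000	8033000	.
TaPP2C127	tri09	A	4A	L	9010000	9013000	.
TaPP2C176	tri09	B	5B	L	9020000	9023000	.
TaPP2C187	tri09	D	5D	L	9030000	9033000	.
TaPP2C224	tri10	A	7A	S	10010000	10013000	.
TaPP2C129	tri10	B	4A	L	10020000	10023000	.
TaPP2C246	tri10	D	7D	S	10030000	10033000	.
TaPP2C194	tri11	A	6A	S	11010000	11013000	.
TaPP2C207	tri11	B	6B	L	11020000	11023000	.
TaPP2C217	tri11	D	6D	S	11030000	11033000	.
TaPP2C195	tri12	A	6A	L	12010000	12013000	.
TaPP2C205	tri12	B	6B	S	12020000	12023000	.
TaPP2C218	tri12	D	6D	L	12030000	12033000	.
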