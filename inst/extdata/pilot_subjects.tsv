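id	group	ca199	stage	cfdna_yield_ng	mean_depth
P01	pdac	120	local	55.4	3819
P02	pdac	120	regional	56.6	4254
P03	pdac	120	systemic	21.5	4121
P04	pdac	120	systemic	50.8	3678
P05	pdac	120	systemic	40.7	4622
P06	pdac	120	systemic	34	4249
P07	pdac	120	systemic	45.8	4028
P08	pdac	120	local	13.3	4103
P09	pdac	120	local	41.5	4264
P10	pdac	120	local	44.1	4028
P11	pdac	120	local	30.7	2795
P12	pdac	120	local	44.8	4106
P13	pdac	120	regional	56.5	3845
P14	pdac	120	regional	19.8	4066
P15	pdac	120	regional	31	4225
P16	pdac	120	regional	56.8	4552
P17	pdac	120	regional	58.8	3701
P18	pdac	120	regional	12.3	4513
P19	pdac	120	regional	31.6	4126
P20	pdac	120	regional	36.3	4407
P21	pdac	120	regional	54.8	4360
P22	pdac	120	regional	13.5	4280
P23	pdac	120	regional	59.4	3575
P24	pdac	120	regional	57.1	3956
P25	pdac	120	regional	10.5	4241
P26	pdac	120	regional	33.8	3611
P27	pdac	120	regional	27.1	3775
P28	pdac	120	regional	54.9	4224
P29	pdac	120	systemic	30.1	4299
P30	pdac	120	systemic	51.1	4178
P31	pdac	120	systemic	45.8	3638
P32	pdac	120	systemic	49.8	3552
P33	pdac	120	systemic	27	4597
P34	pdac	120	systemic	43	4095
P35	pdac	120	systemic	6.2	4027
P36	pdac	120	systemic	51	3944
P37	pdac	15	systemic	6.4	3514
P38	pdac	15	systemic	17.2	4237
P39	pdac	15	systemic	55	3905
P40	pdac	15	unknown	39	3919
H01	healthy	120	NA	26.5	4365
H02	healthy	120	NA	29.5	4321
H03	healthy	120	NA	8	4549
H04	healthy	15	NA	58.6	3802
H05	healthy	15	NA	29.3	4252
H06	healthy	15	NA	57.7	4548
H07	healthy	15	NA	53.9	3548
H08	healthy	15	NA	40.6	3648
H09	healthy	15	NA	58.4	3539
H10	healthy	15	NA	39.4	3408
H11	healthy	15	NA	24	4024
H12	healthy	15	NA	24.7	4253
H13	healthy	15	NA	27.5	4472
H14	healthy	15	NA	48.4	4410
H15	healthy	15	NA	8.1	3591
H16	healthy	15	NA	46.4	4731
H17	healthy	15	NA	42.6	3725
H18	healthy	15	NA	15.2	4034
H19	healthy	15	NA	20.1	3823
H20	healthy	15	NA	33.8	3943
C01	pancreatitis	120	NA	42.5	4067
C02	pancreatitis	120	NA	59.1	4040
C03	pancreatitis	120	NA	47	3982
C04	pancreatitis	120	NA	36.6	4035
C05	pancreatitis	120	NA	51.9	3798
C06	pancreatitis	15	NA	16.2	3790
C07	pancreatitis	15	NA	20.6	3328
C08	pancreatitis	15	NA	50.7	3839
C09	pancreatitis	15	NA	43.4	3787
B01	benign	120	NA	19	5073
B02	benign	120	NA	8.3	3447
B03	benign	120	NA	13.6	4047
B04	benign	120	NA	17.7	3395
B05	benign	120	NA	31.9	3404
B06	benign	120	NA	16.7	4042
B07	benign	120	NA	44.8	3593
B08	benign	120	NA	6.4	3991
B09	benign	120	NA	26.3	3821
B10	benign	120	NA	33.8	3747
B11	benign	120	NA	6.1	3182
B12	benign	15	NA	37.4	3502
B13	benign	15	NA	14.5	4064
B14	benign	15	NA	25.4	4219
B15	benign	15	NA	40.9	3795
B16	benign	15	NA	47.9	3992
B17	benign	15	NA	36.4	4441
B18	benign	15	NA	18.6	4568
B19	benign	15	NA	10.9	3553
B20	benign	15	NA	10.6	3945
B21	benign	15	NA	22.5	4473
B22	benign	15	NA	42	3804
B23	benign	15	NA	6	3971
B24	benign	15	NA	17.3	3958
B25	benign	15	NA	56.4	3637
B26	benign	NA	NA	56	3814
B27	benign	NA	NA	45.6	3980
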