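base	atom	x	y	z
A	P	4.2922	1.3261	-4.8150
A	OP1	3.3810	0.4726	-5.6076
A	OP2	5.7801	0.7148	-4.8649
A	O5'	3.7852	1.3785	-3.2880
A	C5'	3.7967	0.0367	-2.8013
A	C4'	3.3212	0.0155	-1.3478
A	O4'	1.9672	0.5077	-1.2537
A	C3'	3.2520	-1.4347	-0.8217
A	O3'	4.4233	-1.7520	-0.0681
A	C2'	2.0028	-1.4454	0.0879
A	O2'	2.3634	-1.7716	1.4316
A	C1'	1.4642	-0.0004	0.0000
A	N9	0.0000	0.0000	0.0000
A	C8	-0.8062	-1.0988	-0.0003
A	N7	-2.0551	-0.7339	-0.0004
A	C5	-2.1303	0.6180	0.0058
A	C6	-3.1821	1.5499	-0.0011
A	N6	-4.5004	1.1287	-0.0020
A	N1	-2.8823	2.8439	-0.0002
A	C2	-1.6275	3.2536	0.0006
A	N3	-0.6104	2.4186	0.0008
A	C4	-0.8124	1.1057	0.0008
C	P	4.2870	-3.5631	3.5061
C	OP1	3.3757	-3.2195	4.6192
C	OP2	5.7762	-3.0608	3.8553
C	O5'	3.7815	-2.8442	2.1571
C	C5'	3.7947	-1.4390	2.4080
C	C4'	3.3215	-0.6923	1.1603
C	O4'	1.9666	-1.0706	0.8317
C	C3'	3.2533	0.8267	1.4307
C	O3'	4.4265	1.4764	0.9368
C	C2'	2.0036	1.2926	0.6477
C	O2'	2.3667	2.2477	-0.3510
C	C1'	1.4650	-0.0018	0.0002
C	N1	0.0000	0.0000	0.0000
C	C2	-0.6682	1.1662	0.0004
C	O2	-0.0455	2.2153	0.0021
C	N3	-2.0003	1.1962	-0.0009
C	C4	-2.7021	0.0708	-0.0021
C	N4	-4.0767	0.1128	-0.0029
C	C5	-2.0308	-1.1691	0.0024
C	C6	-0.6772	-1.1822	-0.0029
G	P	4.2953	1.3211	-4.8138
G	OP1	3.3851	0.4672	-5.6067
G	OP2	5.7833	0.7087	-4.8630
G	O5'	3.7875	1.3755	-3.2875
G	C5'	3.7981	0.0337	-2.7996
G	C4'	3.3227	0.0132	-1.3466
G	O4'	1.9685	0.5062	-1.2538
G	C3'	3.2522	-1.4356	-0.8198
G	O3'	4.4237	-1.7529	-0.0650
G	C2'	2.0016	-1.4459	0.0896
G	O2'	2.3623	-1.7710	1.4334
G	C1'	1.4647	-0.0011	0.0001
G	N9	0.0000	0.0000	0.0000
G	C8	-0.8055	-1.1014	-0.0000
G	N7	-2.0542	-0.7350	-0.0008
G	C5	-2.1237	0.6190	-0.0013
G	C6	-3.1882	1.5503	-0.0028
G	O6	-4.3477	1.1731	-0.0039
G	N1	-2.8880	2.8672	0.0033
G	C2	-1.5887	3.2763	-0.0024
G	N2	-1.3139	4.6209	-0.0032
G	N3	-0.5910	2.4216	-0.0011
G	C4	-0.8110	1.1020	-0.0004
U	P	4.2940	-3.4500	3.6119
U	OP1	3.3815	-3.0755	4.7147
U	OP2	5.7819	-2.9351	3.9481
U	O5'	3.7877	-2.7715	2.2427
U	C5'	3.7987	-1.3595	2.4522
U	C4'	3.3256	-0.6515	1.1821
U	O4'	1.9698	-1.0411	0.8640
U	C3'	3.2528	0.8752	1.4031
U	O3'	4.4222	1.5128	0.8853
U	C2'	2.0021	1.3135	0.6108
U	O2'	2.3599	2.2389	-0.4182
U	C1'	1.4655	0.0006	-0.0001
U	N1	0.0000	0.0000	0.0000
U	C2	-0.6656	1.1670	0.0042
U	O2	-0.0449	2.2115	0.0027
U	N3	-2.0121	1.1953	-0.0004
U	C4	-2.7157	0.0450	0.0017
U	O4	-3.9335	0.0703	0.0029
U	C5	-2.0262	-1.1902	0.0024
U	C6	-0.6758	-1.1897	0.0013
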