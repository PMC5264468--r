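gene_id	clone	xa_reads	xi_reads	total_reads	xi_pct	tau_i0
ARSD	clone12	238	236	474	49.8	0
ARSD	clone34	284	14	298	4.7	1.52e-06
CA5B	clone12	298	133	431	30.9	0
CA5B	clone34	255	42	297	14.1	0
CDK16	clone12	4232	525	4757	11.0	0
CDK16	clone34	3647	428	4075	10.5	0
CENPI	clone12	167	6	173	3.5	0.0113
CENPI	clone34	114	8	122	6.6	1.11e-05
CXorf40A	clone12	1341	3	1344	0.2	0.9975
CXorf40A	clone34	726	191	917	20.8	0
GEMIN8	clone12	61	46	107	43.0	0
GEMIN8	clone34	83	25	108	23.1	0
GYG2	clone12	73	31	104	29.8	0
GYG2	clone34	27	0	27	0.0	0.9834
HCCS	clone12	23	71	94	75.5	0
HCCS	clone34	221	0	221	0.0	0.9951
MED14	clone12	441	34	475	7.2	0
MED14	clone34	268	15	283	5.3	1.73e-07
MXRA5	clone12	9706	97	9803	1.0	0.0194
MXRA5	clone34	6020	827	6847	12.1	0
PLCXD1	clone12	34	22	56	39.3	0
PLCXD1	clone34	16	35	51	68.6	0
PNPLA4	clone12	106	19	125	15.2	0
PNPLA4	clone34	108	2	110	1.8	0.6737
PRKX	clone12	298	2	300	0.7	0.9898
PRKX	clone34	62	6	68	8.8	2.04e-05
RIBC1	clone12	18	6	24	25.0	1.73e-08
RIBC1	clone34	22	0	22	0.0	0.9812
RP11-1148L6.5	clone12	835	0	835	0.0	0.9998
RP11-1148L6.5	clone34	137	5	142	3.5	0.0153
RP11-706O15.1	clone12	564	24	588	4.1	2.18e-08
RP11-706O15.1	clone34	392	5	397	1.3	0.5506
SYAP1	clone12	45	16	61	26.2	0
SYAP1	clone34	44	6	50	12.0	6.16e-06
TMSB4X	clone12	31358	660	32018	2.1	4.15e-06
TMSB4X	clone34	32145	9	32154	0.0	0.9873
UXT	clone12	48	26	74	35.1	0
UXT	clone34	30	33	63	52.4	0
WASH6P	clone12	13	11	24	45.8	0
WASH6P	clone34	12	10	22	45.5	0
XG	clone12	4868	4337	9205	47.1	0
XG	clone34	3878	561	4439	12.6	0
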