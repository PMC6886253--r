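	A	C	D	E	F	G	H	I	K	L	M	N	P	Q	R	S	T	V	W	Y
A	0	0.631	1.6813	1.8235	1.5534	0.5213	1.5814	1.0198	1.8681	0.9577	1.1465	1.3187	0.8419	1.4925	2.2729	0.632	0.7406	0.7608	2.3759	1.8986
C	0.631	0	1.6835	1.7378	0.9389	1.069	1.2899	0.4918	1.7903	0.3945	0.5433	1.2316	0.8525	1.301	2.0706	0.8051	0.6452	0.3688	1.8315	1.3957
D	1.6813	1.6835	0	0.2616	2.1356	1.5305	1.1356	2.1129	0.2727	2.016	1.6857	0.8399	1.0223	0.8741	0.8081	1.0962	1.1836	2.0311	2.3865	1.8738
E	1.8235	1.7378	0.2616	0	2.0776	1.7256	1.0646	2.1336	0.0773	2.0377	1.6594	0.8852	1.1312	0.8399	0.5577	1.2424	1.2673	2.0857	2.2517	1.7636
F	1.5534	0.9389	2.1356	2.0776	0	1.9421	1.3164	0.7453	2.1238	0.6964	0.4991	1.587	1.4572	1.5048	2.1786	1.5639	1.2621	0.9835	1.056	0.8491
G	0.5213	1.069	1.5305	1.7256	1.9421	0	1.6141	1.511	1.754	1.43	1.5037	1.2234	0.8003	1.4568	2.2199	0.5729	0.8328	1.2683	2.6186	2.1042
H	1.5814	1.2899	1.1356	1.0646	1.3164	1.6141	0	1.6079	1.0715	1.4835	1.0229	0.4985	0.8226	0.2869	1.1361	1.0866	0.8439	1.633	1.3259	0.8027
I	1.0198	0.4918	2.1129	2.1336	0.7453	1.511	1.6079	0	2.1903	0.1353	0.623	1.6587	1.3267	1.6821	2.4029	1.2969	1.1121	0.2826	1.7832	1.4669
K	1.8681	1.7903	0.2727	0.0773	2.1238	1.754	1.0715	2.1903	0	2.092	1.7091	0.8886	1.1586	0.8434	0.5358	1.2768	1.3022	2.1416	2.2702	1.7839
L	0.9577	0.3945	2.016	2.0377	0.6964	1.43	1.4835	0.1353	2.092	0	0.52	1.5333	1.208	1.5586	2.3068	1.1929	0.9915	0.2872	1.7075	1.3663
M	1.1465	0.5433	1.6857	1.6594	0.4991	1.5037	1.0229	0.623	1.7091	0.52	0	1.1801	0.9949	1.1379	1.8518	1.0855	0.7997	0.7474	1.3211	0.911
N	1.3187	1.2316	0.8399	0.8852	1.587	1.2234	0.4985	1.6587	0.8886	1.5333	1.1801	0	0.4773	0.2616	1.178	0.7264	0.6199	1.598	1.7965	1.2574
P	0.8419	0.8525	1.0223	1.1312	1.4572	0.8003	0.8226	1.3267	1.1586	1.208	0.9949	0.4773	0	0.6728	1.5292	0.2725	0.2186	1.2081	1.9393	1.3978
Q	1.4925	1.301	0.8741	0.8399	1.5048	1.4568	0.2869	1.6821	0.8434	1.5586	1.1379	0.2616	0.6728	0	1.0178	0.9274	0.7614	1.6639	1.61	1.0819
R	2.2729	2.0706	0.8081	0.5577	2.1786	2.2199	1.1361	2.4029	0.5358	2.3068	1.8518	1.178	1.5292	1.0178	0	1.6963	1.6351	2.4131	2.1122	1.7092
S	0.632	0.8051	1.0962	1.2424	1.5639	0.5729	1.0866	1.2969	1.2768	1.1929	1.0855	0.7264	0.2725	0.9274	1.6963	0	0.3359	1.1294	2.157	1.6228
T	0.7406	0.6452	1.1836	1.2673	1.2621	0.8328	0.8439	1.1121	1.3022	0.9915	0.7997	0.6199	0.2186	0.7614	1.6351	0.3359	0	1.0036	1.8256	1.2961
V	0.7608	0.3688	2.0311	2.0857	0.9835	1.2683	1.633	0.2826	2.1416	0.2872	0.7474	1.598	1.2081	1.6639	2.4131	1.1294	1.0036	0	1.9845	1.6178
W	2.3759	1.8315	2.3865	2.2517	1.056	2.6186	1.3259	1.7832	2.2702	1.7075	1.3211	1.7965	1.9393	1.61	2.1122	2.157	1.8256	1.9845	0	0.5472
Y	1.8986	1.3957	1.8738	1.7636	0.8491	2.1042	0.8027	1.4669	1.7839	1.3663	0.911	1.2574	1.3978	1.0819	1.7092	1.6228	1.2961	1.6178	0.5472	0
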