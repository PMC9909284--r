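#format=pgxkb-1 build=GRCh38
gene	haplotype	AAC	AME	SAS	EAS	EUR	LAT	NEA	OCE	SSA
CYP2B6	*1		0.001025	0.003283	0.17746	0.028458	0.004662	0.241698	0.040587	0.001051
CYP2B6	*2	0.496215		0.025472	0.102595	0.13722	0.020769	0.342504	0.042307	0.61727
CYP2B6	*3	0.262169	0.381739	0.421737	0.021946	0.204813	0.32002	0.117703	0.913063	0.377248
CYP2B6	*4	0.238956	0.08227	0.549506	0.697997	0.629507	0.654546	0.298093	0.004041	0.004429
CYP2C19	*1	0.004432	0.000185	0.06676	0.022738	0.478955	0.125999	0.722417	0.019677	0.035526
CYP2C19	*2	0.613204	0.127716		0.055561	0.221513	0.52126	0.249758	0.622247	0.634979
CYP2C19	*3	0.000504	0.828696	0.096351		0.15253	0.267584	0.015344	0.225868	0.000385
CYP2C19	*4	0.381858	0.0434	0.152976	0.431687	0.147	0.085155	0.012479	0.132206	
CYP2C8	*1		0.866599	0.085563		0.01939	0.985259	0.180707	0.086944	0.57469
CYP2C8	*2	0.096261	0.132875	0.802288	0.03092	0.08144	0.014422	0.702402	0.766831	0.157843
CYP2C8	*3	0.001888	0.000524	0.112148	0.00165	0.899169	0.000318	0.116889		0.267466
CYP2C9	*1	0.048368	0.008849	0.001727		0.246012	0.038145	0.000294	0.600688	0.000164
CYP2C9	*2	0.191401	0.236223	0.028376	0.112342		0.000129	0.32902	0.266871	0.248338
CYP2C9	*3	0.106707	0.256894	0.134488	0.058199	0.098172	0.249738	0.120303	0.007719	
CYP2C9	*4	0.032261	0.384224		0.042436	0.500961	0.059818	0.241012	0.102335	0.097339
CYP2C9	*5	0.546293	0.080264	0.120126	0.646598	0.006437	0.559452	0.117916	0.010193	0.274932
CYP2C9	*6	0.01888	0.030433	0.519636	0.00144	0.144252	0.003671	0.021486	0.012168	0.21101
CYP2C9	*7	0.056087	0.003111	0.009237	0.004809	0.000115	0.089044	0.169966	0.000023	0.167631
CYP2D6	*1	0.284192	0.052773	0.131854	0.065191	0.028445			0.155912	0.263225
CYP2D6	*2	0.307533	0.064518	0.114161	0.074658	0.862057	0.154088	0.10752	0.305374	0.00932
CYP2D6	*3	0.322354	0.58276	0.49562	0.008666	0.078048	0.280507	0.37092	0.007269	0.023796
CYP2D6	*4	0.04795	0.209741	0.143402	0.680665	0.000142	0.002956	0.014988		0.024727
CYP2D6	*5	0.037969	0.090205	0.11496	0.170817	0.031305		0.042066	0.099476	0.678929
CYP3A4	*1	0.007916	0.061511	0.295865	0.014832	0.003209	0.091913	0.769699	0.333074	0.048429
CYP3A4	*2	0.50256	0.111141	0.004411	0.118513	0.09279	0.616247	0.000284	0.072737	0.59247
CYP3A4	*3	0.169929	0.210734	0.051787	0.027492	0.040412	0	0.03106	0.000848	
CYP3A4	*4	0.273471	0.615824	0.39728	0.716684	0.854456	0.22897	0.003848	0.463675	0.016279
CYP3A4	*5	0.046121		0.250655	0.122476	0.00913	0.062867	0.195107	0.129663	0.236013
CYP3A5	*1		0.334593	0.164566		0.097802	0.094115	0.000315	0.126965	0.165796
CYP3A5	*2	0.000084	0.022311	0.009728	0.002961	0.751428	0.079659	0.012057	0.003555	0.058533
CYP3A5	*3	0.095751	0.116384	0.010015	0.679909	0.111008	0.096831	0.163635	0.26016	
CYP3A5	*4	0.018544	0.074215	0.114228	0.012341	0.000006	0.135602		0.079444	0.439302
CYP3A5	*5	0.081566	0.316235	0.575828	0.118267	0.019509	0.013983	0.242139	0.022172	0.170878
CYP3A5	*6	0.007091	0.000762	0.009419	0.031925	0.005896	0.08912		0.004794	0.092243
CYP3A5	*7	0.288312	0.135496	0.116212	0.147357	0.014347	0.490688	0.262837	0.502906	0.026248
CYP4F2	*1	0.392469	0.01756	0.028418	0.38107	0.169831	0.051149		0.362152	
CYP4F2	*2	0.160656		0.620768	0.020582	0.312896	0.000179		0.040834	0.000864
CYP4F2	*3	0.02279	0.494349	0.015622	0.0715	0.06815	0.465799	0.046548	0.19835	0.038751
CYP4F2	*4	0.084059	0.025517	0.08295	0.022887	0.013732	0.234892	0.27565	0.09305	0.005827
CYP4F2	*5	0.325669	0.010765	0.16959		0.076975	0.077643	0.009466	0.078705	0.341038
CYP4F2	*6	0.014355	0.432461	0.082649	0.008553	0.358413	0.170334	0.107717	0.226907	0.605069
DPYD	*1	0.070631	0.355079	0.121703	0.847644	0.551118	0.022597	0.575265	0.02317	
DPYD	*2	0.303876		0.240643	0.015472	0.044179	0.356658	0.174091	0.002653	0.808452
DPYD	*3		0.383973	0.072758	0.041489	0.391617	0.564533	0.000044	0.248432	0.188941
DPYD	*4	0.187042	0.000099	0.564893	0.095393	0.013084	0.05621	0.250598	0.725743	0.002372
NUDT15	*1	0.012808	0.002284	0.061762	0.733948	0.006045	0.021753	0.02496	0.671861	0.0069
NUDT15	*2	0.0091	0.023171	0.516835	0.038565	0.367213	0.448789	0.021099	0.011559	0.140295
NUDT15	*3	0.270953	0.001721	0.019069	0.10847	0.044709	0.296298	0.155248	0.000009	0.139508
NUDT15	*4	0.367423	0.415719	0.310085	0.017922	0.146403	0.113763	0.355747	0.093566	0.203386
NUDT15	*5	0.21153	0.300286	0.005421	0.097999	0.201179	0.077015	0.053985	0.222757	0.093159
NUDT15	*6	0.128183			0.003093	0.234447	0.042378	0.388959	0.000245	0.416749
SLCO1B1	*1	0.031687	0.059249		0.387572		0.661072	0.000997	0.289392	
SLCO1B1	*2	0.915889	0.559067	0.173167	0.07604		0.09633	0.195239	0.611605	0.032893
SLCO1B1	*3	0.04643	0.057801		0.251656	0.384461	0.105977	0.212599	0.098294	0.52466
SLCO1B1	*4		0.323881	0.494757	0.28473	0.209992	0.136619	0.591162	0.000707	0.16264
TPMT	*1	0.005255		0.05165		0.065015	0.184827	0.178211	0.000658	0.01573
TPMT	*2	0.0813	0.087069	0.193843	0.060963	0.058198	0.009923	0.106719	0.077873	0.019339
TPMT	*3	0.888184	0.184298	0.022505	0.416673	0.012321	0.046176	0.339508	0.143513	0.017828
TPMT	*4		0.049105	0.336781	0.000004	0.162087	0.492742	0.016809		0.020206
TPMT	*5	0.000186	0.346236	0.224605	0.11327	0.62434	0.015963	0.049877		0.351073
TPMT	*6	0.00004	0.000035		0.181389	0.078035	0.250365	0.308874		0.575821
UGT1A1	*1	0.003869	0.031753	0.072965	0.030923	0.002701	0.254255	0.799577	0.005223	
UGT1A1	*2		0.013388	0.619569	0.308373	0.707125	0.103844	0.009019	0.00168	0.321107
UGT1A1	*3	0.068653	0.000357		0.152691	0.085239	0.043136	0.009774	0.340358	0.056604
UGT1A1	*4	0.027424	0.648438	0.016666	0.037173	0.064626	0.296396	0.112733	0.000825	0.280621
UGT1A1	*5	0.015847	0.259255	0.065885	0.448899	0.04451	0.041214	0.027668	0.054959	0.04722
UGT1A1	*6	0.667714	0.046807	0.05006	0.021938	0.095796	0.261151	0.041226	0.596952	0.03517
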