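sample_id	bacteria	archaea	eukaryota	viruses	unassigned
S0001	1674	286	20	10	10
S0002	1687	268	27	7	11
S0003	1664	287	26	13	10
S0004	1610	340	24	11	15
S0005	1616	324	32	14	14
S0006	1647	299	27	13	14
S0007	1628	323	25	12	12
S0008	1654	305	19	13	9
S0009	1647	298	23	19	13
S0010	1658	291	21	17	13
S0011	1660	296	22	11	11
S0012	1681	283	17	13	6
S0013	1925	21	31	16	7
S0014	1933	21	29	9	8
S0015	1933	24	25	6	12
S0016	1932	19	19	12	18
S0017	1927	19	27	8	19
S0018	1936	19	18	12	15
S0019	1936	18	21	14	11
S0020	1924	18	30	20	8
S0021	1935	18	26	13	8
S0022	1924	30	25	10	11
S0023	1931	21	26	10	12
S0024	1922	28	30	8	12
S0025	1947	17	19	4	13
S0026	1941	17	17	14	11
S0027	1930	25	24	12	9
S0028	1931	22	23	13	11
S0029	1921	21	27	14	17
S0030	1928	18	32	8	14
S0031	1922	19	31	11	17
S0032	1938	24	16	10	12
S0033	1941	16	16	11	16
S0034	1927	24	22	11	16
S0035	1919	25	30	13	13
S0036	1941	24	19	7	9
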