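strain_id	reference_id	assay	replicate	t0_mutant	t0_reference	t1_mutant	t1_reference	dilution_t0	dilution_t1	generations	provenance
PFL_3078-promoter	WspF-V271G-GFP	competition	1	5070	4930	2731	7269	1	1	10	synthetic
PFL_3078-promoter	WspF-V271G-GFP	competition	2	5075	4925	2660	7340	1	1	10	synthetic
PFL_3078-promoter	WspF-V271G-GFP	competition	3	4983	5017	2685	7315	1	1	10	synthetic
PFL_3078-promoter	WspF-V271G-GFP	competition	4	5036	4964	2706	7294	1	1	10	synthetic
MwsR-R1000C	WspF-V271G-GFP	competition	1	4946	5054	5473	4527	1	1	10	synthetic
MwsR-R1000C	WspF-V271G-GFP	competition	2	4969	5031	5493	4507	1	1	10	synthetic
MwsR-R1000C	WspF-V271G-GFP	competition	3	4994	5006	5511	4489	1	1	10	synthetic
MwsR-R1000C	WspF-V271G-GFP	competition	4	4953	5047	5516	4484	1	1	10	synthetic
AwsX-del40	WspF-V271G-GFP	competition	1	4974	5026	5046	4954	1	1	10	synthetic
AwsX-del40	WspF-V271G-GFP	competition	2	5032	4968	4991	5009	1	1	10	synthetic
AwsX-del40	WspF-V271G-GFP	competition	3	5015	4985	5011	4989	1	1	10	synthetic
AwsX-del40	WspF-V271G-GFP	competition	4	4963	5037	4914	5086	1	1	10	synthetic
WspE-P570L	WspF-V271G-GFP	competition	1	5054	4946	5341	4659	1	1	10	synthetic
WspE-P570L	WspF-V271G-GFP	competition	2	4908	5092	5164	4836	1	1	10	synthetic
WspE-P570L	WspF-V271G-GFP	competition	3	4978	5022	5270	4730	1	1	10	synthetic
WspE-P570L	WspF-V271G-GFP	competition	4	5040	4960	5281	4719	1	1	10	synthetic
PFL_0087-G310D	WspF-V271G-GFP	competition	1	5157	4843	3770	6230	1	1	10	synthetic
PFL_0087-G310D	WspF-V271G-GFP	competition	2	5053	4947	3691	6309	1	1	10	synthetic
PFL_0087-G310D	WspF-V271G-GFP	competition	3	5003	4997	3807	6193	1	1	10	synthetic
PFL_0087-G310D	WspF-V271G-GFP	competition	4	5046	4954	3826	6174	1	1	10	synthetic
WspA-del293	WspF-V271G-GFP	competition	1	4994	5006	3992	6008	1	1	10	synthetic
WspA-del293	WspF-V271G-GFP	competition	2	4988	5012	3969	6031	1	1	10	synthetic
WspA-del293	WspF-V271G-GFP	competition	3	4936	5064	4010	5990	1	1	10	synthetic
WspA-del293	WspF-V271G-GFP	competition	4	5060	4940	3951	6049	1	1	10	synthetic
ancestral-WT	WspF-V271G-GFP	competition	1	4953	5047	26	9974	1	1	10	synthetic
ancestral-WT	WspF-V271G-GFP	competition	2	5008	4992	21	9979	1	1	10	synthetic
ancestral-WT	WspF-V271G-GFP	competition	3	4996	5004	23	9977	1	1	10	synthetic
ancestral-WT	WspF-V271G-GFP	competition	4	5060	4940	25	9975	1	1	10	synthetic
WspF-V271G	WT-GFP	invasion	1	87	9913	1613	8387	1	1	10	synthetic
WspF-V271G	WT-GFP	invasion	2	88	9912	1666	8334	1	1	10	synthetic
WspF-V271G	WT-GFP	invasion	3	98	9902	1690	8310	1	1	10	synthetic
WspF-V271G	WT-GFP	invasion	4	89	9911	1686	8314	1	1	10	synthetic
WspF-V271G	WT-GFP	invasion	5	118	9882	1653	8347	1	1	10	synthetic
WspF-V271G	WT-GFP	invasion	6	104	9896	1663	8337	1	1	10	synthetic
MwsR-R1000C	WT-GFP	invasion	1	94	9906	1972	8028	1	1	10	synthetic
MwsR-R1000C	WT-GFP	invasion	2	109	9891	2022	7978	1	1	10	synthetic
MwsR-R1000C	WT-GFP	invasion	3	85	9915	1989	8011	1	1	10	synthetic
MwsR-R1000C	WT-GFP	invasion	4	98	9902	1979	8021	1	1	10	synthetic
MwsR-R1000C	WT-GFP	invasion	5	106	9894	1919	8081	1	1	10	synthetic
MwsR-R1000C	WT-GFP	invasion	6	101	9899	1983	8017	1	1	10	synthetic
AwsX-del40	WT-GFP	invasion	1	94	9906	1419	8581	1	1	10	synthetic
AwsX-del40	WT-GFP	invasion	2	108	9892	1420	8580	1	1	10	synthetic
AwsX-del40	WT-GFP	invasion	3	81	9919	1420	8580	1	1	10	synthetic
AwsX-del40	WT-GFP	invasion	4	103	9897	1435	8565	1	1	10	synthetic
AwsX-del40	WT-GFP	invasion	5	110	9890	1403	8597	1	1	10	synthetic
AwsX-del40	WT-GFP	invasion	6	108	9892	1408	8592	1	1	10	synthetic
PFL_3078-promoter	WT-GFP	invasion	1	93	9907	679	9321	1	1	10	synthetic
PFL_3078-promoter	WT-GFP	invasion	2	99	9901	733	9267	1	1	10	synthetic
PFL_3078-promoter	WT-GFP	invasion	3	133	9867	700	9300	1	1	10	synthetic
PFL_3078-promoter	WT-GFP	invasion	4	105	9895	683	9317	1	1	10	synthetic
PFL_3078-promoter	WT-GFP	invasion	5	114	9886	660	9340	1	1	10	synthetic
PFL_3078-promoter	WT-GFP	invasion	6	99	9901	706	9294	1	1	10	synthetic
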