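isolate_id	experiment	gene_name	coord_system	position	ref	alt	structural_flag	provenance
WS01	wt	wspF	cds_nt	812	T	G		main_text
WS02	wt	wspF	cds_nt	812	T	G		main_text
WS03	wt	wspF	cds_nt	812	T	G		main_text
WS04	wt	wspF	cds_nt	812	T	G		main_text
WS05	wt	wspF	cds_nt	812	T	G		main_text
WS06	wt	wspF	cds_nt	812	T	G		main_text
WS07	wt	wspF	cds_nt	812	T	G		main_text
WS08	wt	wspF	cds_nt	812	T	G		main_text
WS09	wt	wspF	cds_nt	812	T	G		main_text
WS10	wt	wspF	cds_nt	812	T	G		main_text
WS11	wt	wspF	cds_nt	812	T	G		main_text
WS12	wt	wspF	cds_nt	179	G	A		reconstructed
WS13	wt	wspF	cds_nt	400	G			reconstructed
WS14	wt	wspF	cds_nt	719	C	A		reconstructed
WS15	wt	wspF	cds_nt	449	A	G		reconstructed
WS16	wt	wspE	cds_nt	1709	C	T		reconstructed
WS17	wt	awsX	cds_nt	118	GTCTGGACA			reconstructed
WS18	wt	awsX	cds_nt	118	GTCTGGACA			reconstructed
WS19	wt	awsX	cds_nt	118	GTCTGGACA			reconstructed
WS20	wt	awsX	cds_nt	223	GTG			reconstructed
WS21	wt	awsX	cds_nt	223	GTG			reconstructed
WS22	wt	awsX	cds_nt	298	GGCACC			reconstructed
WS23	wt	awsX	cds_nt	298	GGCACC			reconstructed
WS24	wt	awsX	cds_nt	89	T	C		reconstructed
WS25	wt	awsX	cds_nt	359	G	T		reconstructed
WS26	wt	awsR	cds_nt	133	A	C		reconstructed
WS27	wt	awsR	cds_nt	239	C	A		reconstructed
WS28	wt	awsR	cds_nt	899	A	G		reconstructed
WS29	wt	awsX	upstream_nt	-120			promoter_capture	main_text
WS30	wt	awsX	upstream_nt	-120			promoter_capture	main_text
WS31	wt	mwsR	cds_nt	2998	C	T		reconstructed
WS32	wt	mwsR	cds_nt	2998	C	T		reconstructed
WS33	wt	mwsR	cds_nt	2998	C	T		reconstructed
WS34	wt	mwsR	cds_nt	3059	G	A		reconstructed
WS35	wt	mwsR	cds_nt	3059	G	A		reconstructed
WS36	wt	mwsR	cds_nt	2639	T	G		reconstructed
WS37	wt	mwsR	cds_nt	2639	T	G		reconstructed
WS38	wt	mwsR	cds_nt	2698	G	A		reconstructed
WS39	wt	mwsR	cds_nt	1498	G	A		reconstructed
WS40	wt	mwsR	cds_nt	1498	G	A		reconstructed
WS41	wt	PFL_3078	upstream_nt	-35	C	T		reconstructed
WS42	wt	PFL_3078	upstream_nt	-35	C	T		reconstructed
WS43	wt	PFL_3078	upstream_nt	-60	G	A		reconstructed
TD44	triple_deletion	dgcH	cds_nt	299	G	A		reconstructed
TD45	triple_deletion	dgcH	cds_nt	929	G	A		reconstructed
TD46	triple_deletion	dgcH	cds_nt	929	G	A		reconstructed
TD47	triple_deletion	dgcH	cds_nt	958	C	T		reconstructed
TD48	triple_deletion	dgcH	cds_nt	988	G	A		reconstructed
TD49	triple_deletion	dgcH	cds_nt	600	G			reconstructed
TD50	triple_deletion	PFL_3078	upstream_nt	-35	C	T		reconstructed
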