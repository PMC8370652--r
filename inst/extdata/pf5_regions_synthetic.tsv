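gene_name	kind	start	end	allowed_classes	provenance
wspA	aa_range	270	310	missense	reconstructed
wspA	aa_range	480	500	inframe_indel	reconstructed
wspF	aa_range	2	337	nonsense,frameshift_indel,inframe_indel	reconstructed
wspF	aa_range	80	120	missense	reconstructed
wspF	aa_range	230	280	missense	reconstructed
wspE	aa_range	550	600	missense	reconstructed
wspR	aa_range	170	185	missense	reconstructed
awsX	aa_range	2	146	inframe_indel,missense	reconstructed
awsR	aa_range	25	100	missense	reconstructed
awsO	aa_range	40	60	missense	reconstructed
mwsR	aa_range	860	910	missense	reconstructed
mwsR	aa_range	990	1070	missense	reconstructed
dgcH	aa_range	300	350	missense	reconstructed
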