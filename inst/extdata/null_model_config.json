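{"rates":{"substitution":1,"indel":1.30572085077165,"promoter_point":0},"gene_weights":{"dgcH":0},"normalization_scope":"three_pathways","calibration":"indel:substitution ratio calibrated once (uniroot) so the Wsp pathway marginal equals 0.54 on the frozen synthetic gene/region fixtures; all other structure is forward-predicted. rho = 1.305721"}
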