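# Default currency metabolites (KEGG compound ids): ubiquitous co-factors
# whose high degree creates biochemically meaningless shortcuts in simple
# graph projections. Edit or extend per analysis.
C00001	H2O
C00002	ATP
C00003	NAD+
C00004	NADH
C00005	NADPH
C00006	NADP+
C00008	ADP
C00009	Orthophosphate
C00010	CoA
C00011	CO2
C00013	Diphosphate
C00014	Ammonia
C00080	H+
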