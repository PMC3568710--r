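feature_id	delta
exon_001	0
exon_002	0
exon_003	0
exon_004	1
exon_005	0
exon_006	0
exon_007	0
exon_008	0
exon_009	0
exon_010	0
exon_011	0
exon_012	1
exon_013	0
exon_014	0
exon_015	0
exon_016	0
exon_017	0
exon_018	0
exon_019	0
exon_020	0
exon_021	0
exon_022	0
exon_023	1
exon_024	0
exon_025	0
exon_026	0
exon_027	0
exon_028	0
exon_029	0
exon_030	0
exon_031	0
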