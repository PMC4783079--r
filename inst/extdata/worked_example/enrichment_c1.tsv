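pathway_id	direction	p_rep	q	overlap	significant
pwA	up	0.006747638326585695	0.04048582995951417	3	TRUE
pwA	down	1.0	1.0	0	FALSE
pwB	up	1.0	1.0	0	FALSE
pwB	down	0.08771929824561403	0.2631578947368421	2	FALSE
pwC	up	0.8100208768267223	1.0	1	FALSE
pwC	down	1.0	1.0	0	FALSE
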