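seq_id	length_bp	gc_percent	g4_count	printed_density_per_kbp	compartment
PN1	27822162	36.0	26041	0.94	nuclear
PN2	20941263	35.2	21555	1.03	nuclear
PN3	21317290	34.8	18839	0.88	nuclear
PN4	25934928	34.7	25232	0.97	nuclear
PN5	26899771	35.3	27761	1.03	nuclear
PN6	24571969	35.5	23639	0.96	nuclear
PN7	31654362	34.8	28552	0.90	nuclear
PN8	23763023	35.0	26679	1.12	nuclear
PN9	24372199	34.1	22262	0.91	nuclear
PN10	27504061	35.6	25068	0.91	nuclear
PN11	20048508	35.0	22253	1.11	nuclear
PN12	24706008	34.8	24271	0.98	nuclear
PN13	29842242	34.5	28749	0.96	nuclear
PN14	30475315	34.5	29451	0.97	nuclear
PN15	23565456	35.4	22321	0.95	nuclear
PN16	27608946	36.0	21207	0.77	nuclear
PN17	19942836	35.4	20337	1.02	nuclear
PN18	36684271	34.7	32786	0.89	nuclear
PN19	27218600	35.1	20810	0.76	nuclear
mitochondrion	774663	44.1	1092	1.41	organelle
chloroplast	145134	36.7	105	0.72	organelle
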