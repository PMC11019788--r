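# Literature-derived reference profile: 29 representative human-gut species
# shared by the core/accessory microbiota of all four WHO age groups in a
# pooled 6,653-sample shallow-shotgun cohort (G1 0-4 y, G2 5-17 y, G3 18-64 y,
# G4 65+ y). prev_* = prevalence (%), abund_* = mean relative abundance over
# all group samples (%), core_* = 1 if the cell was reported as core
# (prevalence >= 50% and mean relative abundance > 0.1%).
# named_species = 0 for per-genus "unknown_species" aggregate bins.
taxon	named_species	prev_G1	prev_G2	prev_G3	prev_G4	abund_G1	abund_G2	abund_G3	abund_G4	core_G1	core_G2	core_G3	core_G4
Bifidobacterium longum	1	69.71	75.68	36.17	41.44	9.03	2.53	0.55	1.52	1	1	0	0
Escherichia coli	1	64.84	43.44	58.51	54.77	6.69	0.87	1.33	2.26	1	0	1	1
Bacteroides unknown_species	0	56.97	96.72	92.90	88.47	0.66	1.23	1.23	1.19	1	1	1	1
Clostridium unknown_species	0	56.84	96.45	96.12	95.86	0.48	0.53	0.60	0.58	1	1	1	1
Blautia unknown_species	0	53.42	98.09	98.52	98.38	0.58	1.57	2.08	1.57	1	1	1	1
Bacteroides uniformis	1	51.81	94.54	89.40	88.29	2.99	4.10	3.40	4.10	1	1	1	1
Ruminococcus unknown_species	0	50.58	97.81	97.26	97.48	0.45	1.54	1.68	1.67	1	1	1	1
Blautia wexlerae	1	48.39	92.62	87.42	84.50	1.82	1.77	1.68	1.45	0	1	1	1
Bifidobacterium unknown_species	0	46.87	60.93	31.08	42.16	0.58	0.29	0.11	0.19	0	1	0	0
Flavonifractor plautii	1	46.87	83.33	66.53	78.38	0.57	0.37	0.29	0.40	0	1	1	1
Phocaeicola vulgatus	1	42.06	84.43	72.49	73.69	1.31	1.44	1.15	1.12	0	1	1	1
Bacteroides thetaiotaomicron	1	40.90	84.70	72.72	73.87	0.82	0.78	0.59	0.74	0	1	1	1
Phocaeicola dorei	1	39.45	80.60	63.11	66.13	2.05	1.51	1.29	1.37	0	1	1	1
Eubacterium unknown_species	0	38.71	94.54	95.90	95.86	0.26	0.99	1.48	1.29	0	1	1	1
Parabacteroides distasonis	1	37.84	82.51	69.38	77.48	1.67	1.15	0.87	1.07	0	1	1	1
Enterocloster unknown_species	0	37.23	87.98	90.35	89.55	0.12	0.16	0.22	0.21	0	1	1	1
Roseburia unknown_species	0	36.74	93.72	95.59	94.05	0.22	0.59	1.14	0.84	0	1	1	1
Faecalibacterium unknown_species	0	36.65	93.44	96.01	94.77	1.17	4.11	3.23	3.39	0	1	1	1
Faecalibacterium prausnitzii	1	36.35	92.62	96.05	93.69	0.97	3.41	2.94	3.12	0	1	1	1
Bacteroides xylanisolvens	1	35.84	79.78	56.34	64.68	0.52	0.63	0.56	0.55	0	1	1	1
Phocaeicola unknown_species	0	35.68	79.23	79.71	74.59	0.21	0.48	0.65	0.53	0	1	1	1
Anaerostipes hadrus	1	34.35	82.51	63.87	58.38	1.11	1.23	1.09	1.09	0	1	1	1
Bacteroides fragilis	1	33.58	43.44	31.50	37.48	2.99	1.25	0.43	0.78	0	0	0	0
Coprococcus unknown_species	0	33.55	87.43	88.87	86.31	0.14	0.48	0.75	0.58	0	1	1	1
Agathobacter rectalis	1	31.29	90.71	92.86	87.39	0.99	3.23	4.11	2.70	0	1	1	1
Blautia massiliensis	1	31.03	84.70	75.68	72.43	0.41	1.01	0.77	0.62	0	1	1	1
Dorea unknown_species	0	30.77	89.89	89.02	85.95	0.12	0.39	0.58	0.41	0	1	1	1
Bacteroides ovatus	1	30.35	68.58	51.41	51.53	0.44	0.33	0.22	0.23	0	1	1	1
Roseburia intestinalis	1	30.06	80.60	84.38	81.26	0.74	0.65	1.01	0.76	0	1	1	1
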