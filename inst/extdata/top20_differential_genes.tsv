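gene_symbol	p_value	fdr	geom_mean_exp	geom_mean_ctrl	fold_change	trend
Glra1	8.157E-12	1.813E-11	2650.31	56.08	47.26	up
Foxf1a	3.199E-11	3.555E-11	551.13	70.9	7.77	up
Nefh	6.781E-11	5.023E-11	1345.14	343.73	3.91	up
Tppp3	0.0000003	4.896E-05	1202.14	286.92	4.19	up
Ankrd55	0.0000003	4.896E-05	368.15	76.36	4.82	up
Slc17a6	0.0000003	4.896E-05	976.2	174.12	5.61	up
Sncg	0.0000003	4.896E-05	984.48	87.66	11.23	up
Vamp1	0.0000006	7.63E-05	3440.73	956.74	3.6	up
Foxf1a	0.0000006	7.63E-05	380.63	94.12	4.04	up
Adamts9	0.0000012	0.0001141	156.57	56.26	2.78	up
Dennd3	0.0000013	0.0001141	155.66	69.33	2.25	up
Apold1	0.0000013	0.0001141	239.55	84.38	2.84	up
Dock5	0.0000018	0.0001296	180.49	82.61	2.18	up
Prune2	0.0000021	0.0001296	205.25	30.72	6.68	up
Asah2	0.0000022	0.0001296	470.21	158.82	2.96	up
Cd38	0.0000022	0.0001296	400.77	131.11	3.06	up
Cdkn1a	0.0000023	0.0001296	910.32	219.95	4.14	up
Spnb3	0.0000024	0.0001296	341.48	785.22	0.43	down
Ahnak2	0.0000024	0.0001296	201.92	84.16	2.4	up
Slc6a5	0.0000025	0.0001296	2625.3	74.1	35.43	up
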