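cluster	modal	haplogroup	n_modal	n_related	n_cluster	age_rho_years	age_rho_sd	age_asd_years	dys19_dup	DYS389I	DYS389b	DYS390	DYS456	DYS19	DYS458	DYS437	DYS438	DYS448	GATA_H4	DYS391	DYS392	DYS393	DYS439	DYS635
alpha	1	C2b1a2-M48	26	257	67	600	200	580	FALSE	14	17	25	15	16	17	14	10	20	10	10	11	13	11	23
beta	1	C2b1a2-M48	26	257	188	800	200	659	TRUE	14	17	24	15	16	18	14	10	20	10	9	11	13	11	23
sigma	2	C2*-M217(xM48)	15	138	76	1100	400	1161	FALSE	14	15	23	15	15	18	14	10	21	11	10	11	14	12	21
gamma	2	C2*-M217(xM48)	15	138	53	600	200	704	FALSE	13	15	23	15	15	18	14	10	21	11	10	11	14	11	22
mu	3	C2*-M217(xM48)	12	189	185	1100	300	1298	FALSE	13	16	25	15	16	18	14	10	22	11	10	11	13	10	21
lambda	3	C2*-M217(xM48)	12	189	19	400	100	407	FALSE	13	16	25	15	16	17	14	10	22	12	10	11	13	10	21
delta	4	Q-M242	11	98	97	1400	500	1360	FALSE	13	15	23	17	13	19	14	11	22	11	10	16	13	13	23
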