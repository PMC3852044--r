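family_id	label	class_1	class_2	class_3	change	direction
PF00001	rhodopsin_family	221	108	205	97	expanded
PF01454	melanoma_associated_antigen	11	18	45	27	expanded
PF00433	protein_kinase_C	26	1	27	26	expanded
PF02093	gag_p30_core_shell	1	1	27	26	expanded
PF00012	hsp70	13	0	23	23	expanded
PF01849	NAC_domain	4	2	20	18	expanded
PF00276	ribosomal_L23	1	1	16	15	expanded
PF01282	ribosomal_S24e	2	2	16	14	expanded
PF05712	mortality_factor_4	2	2	13	11	expanded
PF00261	tropomyosin	5	0	10	10	expanded
PF00153	mitochondrial_carrier	46	8	17	9	expanded
PF00118	tcp1_cpn60_chaperonin	12	2	10	8	expanded
PF00183	hsp90	4	0	8	8	expanded
PF01015	ribosomal_S3Ae	1	1	9	8	expanded
PF01873	IF2B_IF5_domain	2	0	8	8	expanded
PF13853	olfactory_receptor	293	852	691	161	contracted
PF03402	vomeronasal_organ_receptor	2	99	3	96	contracted
PF00003	class_C_GPCR	14	72	17	55	contracted
PF00028	cadherin	50	38	4	34	contracted
PF05296	mammalian_taste_receptor	4	32	2	30	contracted
PF08391	ly49_like	1	21	0	21	contracted
PF02994	L1_transposable_element	0	20	0	20	contracted
PF01157	ribosomal_L21e	1	32	13	19	contracted
PF13885	high_sulfur_B2	3	12	1	11	contracted
PF13841	beta_defensin	7	11	0	11	contracted
PF01198	ribosomal_L31e	1	16	6	10	contracted
PF01779	ribosomal_L29e	1	10	1	9	contracted
PF12774	chaperone_like_ATPases	1	9	0	9	contracted
PF00879	defensin_propeptide	0	9	1	8	contracted
PF00618	ras_like_small_GTPase	0	8	0	8	contracted
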