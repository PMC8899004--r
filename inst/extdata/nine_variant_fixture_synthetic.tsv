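row_id	group	category	gene_symbol	chrom	pos	ref	alt	consequence	protein_change	clinvar_assertion	gnomad_af	kg_af	polyphen_call	sift_call	cadd_phred	fathmm_call	expected_label	manual_codes
C1	case	ecv_only	SCN5A	3	38613773	G	A	missense_variant	p.Arg225Trp	path_or_lp	1.28e-4		probably_damaging	deleterious	28	damaging	Pathogenic	PS1,PM1
C2	case	both	CRYAB	11	111908822	G	A	missense_variant	p.Arg157His	vus	6.15e-5		probably_damaging	deleterious	26	damaging	Likely pathogenic	PS1
C3	case	t1_only	CRYAB	11	111911722	G	A	start_lost	p.Met1Ile	conflicting	9.84e-4				24		Likely pathogenic	PM1,PM5
C4	case	both	MYH7	14	23424839	G	A	missense_variant	p.Arg870His	pathogenic	1.55e-5		probably_damaging	deleterious	29	damaging	Likely pathogenic	PS1
C5	case	t1_only	MYH7	14	23429037	C	T	missense_variant	p.Arg442His	conflicting	6.15e-5		probably_damaging	deleterious	27	damaging	Likely pathogenic	PS1
C6	case	ecv_only	MYBPC3	11	47337543	G	A	missense_variant	p.Arg817Gln	conflicting	2.83e-5		possibly_damaging	deleterious	25	damaging	VUS+	PM1
C7	case	both	MYBPC3	11	47337792	G	A	missense_variant	p.Val771Met	conflicting	1.76e-5		probably_damaging	deleterious	24	damaging	VUS+	PM1
N1	control	control	MYL2	12	110914290	C	T	missense_variant	p.Gly57Glu	vus	2.89e-5		probably_damaging	deleterious	26	damaging	Likely pathogenic	PS1
N2	control	control	TNNT2	1	201365261	G	A	missense_variant	p.Ala114Val	conflicting	1.76e-5		probably_damaging	deleterious	25	damaging	VUS+	PM1
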