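id	enzyme	node	irreversible	transport	equation
R_GLY	glycolysis (lumped; EC 2.7.1.1 ... 2.7.1.40)	gly	TRUE	FALSE	glc_c + 2 adp_c + 2 pi_c + 2 nad_c + 2 buf_c = 2 pyr_c + 2 atp_c + 2 nadh_c + 2 h2o_c + 2 hbuf_c
R_LDH	lactate dehydrogenase (EC 1.1.1.27)	gly	FALSE	FALSE	pyr_c + nadh_c + hbuf_c = lac_c + nad_c + buf_c
T_GLC		gly	FALSE	TRUE	glc_e = glc_c
T_LAC		gly	FALSE	TRUE	lac_c = lac_e
R_PDH	pyruvate dehydrogenase (EC 1.2.4.1)	krb	TRUE	FALSE	pyr_c + nad_c + coa_c + buf_c = nadh_c + co2_c + accoa_c + hbuf_c
R_TCA	Krebs cycle (lumped; EC 1.2.4.1 ... 6.2.1.4)	krb	TRUE	FALSE	pyr_c + adp_c + pi_c + 5 nad_c + 2 h2o_c + 5 buf_c = atp_c + 5 nadh_c + 3 co2_c + 5 hbuf_c
R_OXP	oxidative phosphorylation (lumped ETC + ATP synthase)	oxp	TRUE	FALSE	5 adp_c + 5 pi_c + 2 nadh_c + 2 hbuf_c + o2_m = 5 atp_c + 2 nad_c + 7 h2o_c + 2 buf_c
R_LEAK	ETC electron leak to superoxide	oxp	TRUE	FALSE	nadh_c + buf_c + 2 o2_m = nad_c + hbuf_c + 2 o2s_m
T_O2M		oxp	FALSE	TRUE	o2_c = o2_m
R_ADA	adenosine deaminase + nucleosidase (lumped; EC 3.5.4.4)	pur	FALSE	FALSE	2 h2o_c + ado_c = hpx_c + rib_c + nh3_c
R_XO1	xanthine oxidase (EC 1.17.3.2)	pur	TRUE	FALSE	h2o_c + hpx_c + 2 o2_c + 2 buf_c = xan_c + 2 o2s_c + 2 hbuf_c
R_XO2	xanthine oxidase (EC 1.17.3.2)	pur	TRUE	FALSE	h2o_c + xan_c + 2 o2_c + 2 buf_c = ura_c + 2 o2s_c + 2 hbuf_c
T_ADO		pur	FALSE	TRUE	ado_e = ado_c
T_O2C		pur	FALSE	TRUE	o2_e = o2_c
T_O2S		pur	FALSE	TRUE	o2s_c = o2s_m
R_SOD	superoxide dismutase (EC 1.15.1.1)	ros	TRUE	FALSE	2 h_c + 2 o2s_m = o2_m + h2o2_m
R_CAT	catalase (EC 1.11.1.6)	ros	TRUE	FALSE	2 h2o2_m = 2 h2o_c + o2_m
R_GPX	glutathione peroxidase (EC 1.11.1.9)	ros	TRUE	FALSE	h2o2_m + 2 gsh_m = 2 h2o_c + gssg_m
R_GLS	glutaminase (EC 3.5.1.2)	gsx	FALSE	FALSE	h2o_c + gln_c = glu_c + nh3_c
R_GSS	glutathione synthesis (lumped; EC 6.3.2.2 + 6.3.2.3)	gsx	FALSE	FALSE	2 atp_c + glu_c + cys_c + gly_c + hbuf_c = 2 adp_c + 2 pi_c + gsh_c + buf_c
T_GSHE		gsx	FALSE	TRUE	gsh_e = gsh_c
T_GSHM		gsx	TRUE	TRUE	gsh_c = gsh_m
T_GLN		gsx	FALSE	TRUE	gln_e = gln_c
T_CYS		gsx	FALSE	TRUE	cys_e = cys_c
T_GLY		gsx	FALSE	TRUE	gly_e = gly_c
R_ACC	acetyl-CoA carboxylase (EC 6.4.1.2, committed step)	lip	TRUE	FALSE	atp_c + h2o_c + co2_c + accoa_c = adp_c + pi_c + mcoa_c
R_FAS	fatty-acid synthesis (lumped; EC 2.3.1.85)	lip	TRUE	FALSE	2 nadh_c + 2 mcoa_c + 2 hbuf_c = 2 nad_c + 2 co2_c + 2 coa_c + but_c + 2 buf_c
R_MEV	mevalonate synthesis (lumped; EC 2.3.3.10 + 1.1.1.34)	lip	TRUE	FALSE	2 nadh_c + h2o_c + 3 accoa_c + 2 hbuf_c = 2 nad_c + 3 coa_c + mev_c + 2 buf_c
R_BUF_gly	proton buffer (lumped protonation equilibria)	gly	FALSE	FALSE	hbuf_c = h_c + buf_c
R_BUF_krb	proton buffer (lumped protonation equilibria)	krb	FALSE	FALSE	hbuf_c = h_c + buf_c
R_BUF_oxp	proton buffer (lumped protonation equilibria)	oxp	FALSE	FALSE	hbuf_c = h_c + buf_c
R_BUF_pur	proton buffer (lumped protonation equilibria)	pur	FALSE	FALSE	hbuf_c = h_c + buf_c
R_BUF_ros	proton buffer (lumped protonation equilibria)	ros	FALSE	FALSE	hbuf_c = h_c + buf_c
R_BUF_gsx	proton buffer (lumped protonation equilibria)	gsx	FALSE	FALSE	hbuf_c = h_c + buf_c
R_BUF_lip	proton buffer (lumped protonation equilibria)	lip	FALSE	FALSE	hbuf_c = h_c + buf_c
R_BUF_adn	proton buffer (lumped protonation equilibria)	adn	FALSE	FALSE	hbuf_c = h_c + buf_c
R_ADK	adenylate kinase (EC 2.7.4.3)	adn	FALSE	FALSE	2 adp_c = atp_c + amp_c
R_MNT	maintenance ATP load (lumped ATPases)	adn	TRUE	FALSE	atp_c + h2o_c = adp_c + pi_c
R_CAH	carbonic anhydrase (EC 4.2.1.1)	adn	FALSE	FALSE	h2o_c + co2_c = h_c + hco3_c
T_HCO3		adn	FALSE	TRUE	hco3_e = hco3_c
T_CO2		adn	FALSE	TRUE	co2_c = co2_e
T_H2O		adn	FALSE	TRUE	h2o_e = h2o_c
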