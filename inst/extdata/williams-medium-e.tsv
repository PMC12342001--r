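id	name	mass_gL	mw	amount_nmol	conc_mM	asPrinted	percellVolume	medium
glc_e	Glucose	2	180.06	1.234	11.074	TRUE	0.111105552776388	Williams Medium E
gln_e	Glutamine	0.292	146.07	0.2221	1.999	FALSE	0.111105552776388	Williams Medium E
gsh_e	Glutathione	5e-05	307.08	2.22e-05	0.00247	TRUE	0.111105552776388	Williams Medium E
ser_e	L-serine	0.01	105.04	0.1057	0.952	TRUE	0.111105552776388	Williams Medium E
gly_e	Glycine	0.05	75.03	0.074	0.6664	FALSE	0.111105552776388	Williams Medium E
ala_e	L-alanine	0.09	89.09	0.1122	1.0102	FALSE	0.111105552776388	Williams Medium E
arg_e	L-arginine	0.05	174.11	0.0319	0.2872	FALSE	0.111105552776388	Williams Medium E
asp_e	L-aspartate	0.03	133.04	0.025	0.2254	TRUE	0.111105552776388	Williams Medium E
cys_e	L-cysteine	0.04	121.02	0.0367	0.3306	TRUE	0.111105552776388	Williams Medium E
hco3_e	Bicarbonate	2	60.99	3.6432	32.6943	TRUE	0.111105552776388	Williams Medium E
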