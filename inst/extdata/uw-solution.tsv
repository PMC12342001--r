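id	name	conc_mM	amount_nmol	mass_gL	mw	asPrinted	percellVolume	medium
gsh_e	Glutathione	3	3e-04	NA	NA	FALSE	1e-04	UW solution
ado_e	Adenosine	5	5e-04	NA	NA	FALSE	1e-04	UW solution
h2o_e	Water	NA	5.54	NA	NA	FALSE	1e-04	UW solution
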