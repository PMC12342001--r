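id	name	formula	charge	compartment	dGf0	dHf0
glc_e	glucose	C6H12O6	0	e	0	0
lac_e	lactate	C3H6O3	0	e	-29.005851	11.5
gsh_e	glutathione	C10H18N3O6S	1	e	25.541695	44.764977
ado_e	adenosine	C10H13N5O4	0	e	-15	-20
o2_e	oxygen	O2	0	e	0	0
hco3_e	bicarbonate	CHO3	-1	e	-186.713198	41.5
co2_e	carbon dioxide	CO2	0	e	-184.162729	39.882488
gln_e	glutamine	C5H10N2O3	0	e	-6.312295	-51.617512
ser_e	L-serine	C3H7NO3	0	e	-10	-15
gly_e	glycine	C2H5NO2	0	e	-10	-15
ala_e	L-alanine	C3H7NO2	0	e	-10	-15
arg_e	L-arginine	C6H14N4O2	0	e	-10	-15
asp_e	L-aspartate	C4H7NO4	0	e	-10	-15
cys_e	L-cysteine	C3H7NO2S	0	e	-10	-15
h2o_e	water	H2O	0	e	-29.915031	1.617512
glc_c	glucose	C6H12O6	0	c	0	0
pyr_c	pyruvate	C3H4O3	0	c	-90.8496	20.882488
lac_c	lactate	C3H6O3	0	c	-29.005851	11.5
atp_c	ATP	C10H16N5O13P3	0	c	0.415031	-52.617512
adp_c	ADP	C10H15N5O10P2	0	c	-50	-60
amp_c	AMP	C10H14N5O7P	0	c	-97.984956	-67.382488
pi_c	orthophosphate	H3PO4	0	c	-10	-15
nad_c	NAD+	C21H27N7O14P2	1	c	0	0
nadh_c	NADH	C21H28N7O14P2	0	c	111.292623	-9.382488
h_c	proton	H	1	c	0	0
h2o_c	water	H2O	0	c	-29.915031	1.617512
co2_c	carbon dioxide	CO2	0	c	-184.162729	39.882488
hco3_c	bicarbonate	CHO3	-1	c	-186.713198	41.5
gln_c	glutamine	C5H10N2O3	0	c	-6.312295	-51.617512
glu_c	glutamate	C5H9NO4	0	c	-15	-20
cys_c	L-cysteine	C3H7NO2S	0	c	-10	-15
gly_c	glycine	C2H5NO2	0	c	-10	-15
gsh_c	glutathione	C10H18N3O6S	1	c	25.541695	44.764977
ado_c	adenosine	C10H13N5O4	0	c	-15	-20
hpx_c	hypoxanthine	C5H4N4O	0	c	-10.323879	33.235023
xan_c	xanthine	C5H4N4O2	0	c	-21.97743	8.235023
ura_c	urate	C5H4N4O3	0	c	-33.63098	-16.764977
rib_c	ribose	C5H10O5	0	c	-15	-20
nh3_c	ammonia	NH3	0	c	-5	-10
accoa_c	acetyl-CoA	C23H38N7O17P3S	0	c	15.988096	61.382488
coa_c	coenzyme A	C21H36N7O16P3S	0	c	0	0
mcoa_c	malonyl-CoA	C24H38N7O19P3S	0	c	-144.286466	160.264977
but_c	butyrate	C4H8O2	0	c	248.793654	257
mev_c	mevalonate	C6H12O4	0	c	163.495955	362
o2_c	oxygen	O2	0	c	0	0
o2s_c	superoxide	O2	-1	c	89.939553	23.308756
hbuf_c	protonated buffer	C3H5N2	1	c	-38.592088	0
buf_c	buffer base	C3H4N2	0	c	0	0
o2_m	oxygen	O2	0	m	0	0
o2s_m	superoxide	O2	-1	m	89.939553	23.308756
h2o2_m	hydrogen peroxide	H2O2	0	m	7.604192	26.617512
gsh_m	glutathione	C10H18N3O6S	1	m	25.541695	44.764977
gssg_m	glutathione disulfide	C20H34N6O12S2	2	m	81.302613	-83.087558
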