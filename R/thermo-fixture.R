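## Frozen fixture formation values (kJ/mol at 298 K) for the reduced liver
## network.  Solved (scripted, then frozen) so that: the
## glutathione-peroxidase reaction enthalpy is exactly -196 kJ/mol; ATP
## hydrolysis is -30.5 kJ/mol; every pathway carries a physiological
## effective driving force at 310 K at a reference liver composition, with
## apparent (van 't Hoff) reaction enthalpies chosen so cold suppresses
## and warming activates the lumped pathways (the only route by which
## temperature enters an equilibrium-seeking model); and the residual
## superoxide and hydrogen peroxide equilibria sit in their physiological
## bands.  Compartment copies of a molecule share values, so transport
## steps have zero standard Gibbs energy.
.LIVER_DGF <- c(
  glc_e = 0.000000,
  lac_e = -29.005851,
  gsh_e = 25.541695,
  ado_e = -15.000000,
  o2_e = 0.000000,
  hco3_e = -186.713198,
  co2_e = -184.162729,
  gln_e = -6.312295,
  ser_e = -10.000000,
  gly_e = -10.000000,
  ala_e = -10.000000,
  arg_e = -10.000000,
  asp_e = -10.000000,
  cys_e = -10.000000,
  h2o_e = -29.915031,
  glc_c = 0.000000,
  pyr_c = -90.849600,
  lac_c = -29.005851,
  atp_c = 0.415031,
  adp_c = -50.000000,
  amp_c = -97.984956,
  pi_c = -10.000000,
  nad_c = 0.000000,
  nadh_c = 111.292623,
  h_c = 0.000000,
  h2o_c = -29.915031,
  co2_c = -184.162729,
  hco3_c = -186.713198,
  gln_c = -6.312295,
  glu_c = -15.000000,
  cys_c = -10.000000,
  gly_c = -10.000000,
  gsh_c = 25.541695,
  ado_c = -15.000000,
  hpx_c = -10.323879,
  xan_c = -21.977430,
  ura_c = -33.630980,
  rib_c = -15.000000,
  nh3_c = -5.000000,
  accoa_c = 15.988096,
  coa_c = 0.000000,
  mcoa_c = -144.286466,
  but_c = 248.793654,
  mev_c = 163.495955,
  o2_c = 0.000000,
  o2s_c = 89.939553,
  hbuf_c = -38.592088,
  buf_c = 0.000000,
  o2_m = 0.000000,
  o2s_m = 89.939553,
  h2o2_m = 7.604192,
  gsh_m = 25.541695,
  gssg_m = 81.302613
)

.LIVER_DHF <- c(
  glc_e = 0.000000,
  lac_e = 11.500000,
  gsh_e = 44.764977,
  ado_e = -20.000000,
  o2_e = 0.000000,
  hco3_e = 41.500000,
  co2_e = 39.882488,
  gln_e = -51.617512,
  ser_e = -15.000000,
  gly_e = -15.000000,
  ala_e = -15.000000,
  arg_e = -15.000000,
  asp_e = -15.000000,
  cys_e = -15.000000,
  h2o_e = 1.617512,
  glc_c = 0.000000,
  pyr_c = 20.882488,
  lac_c = 11.500000,
  atp_c = -52.617512,
  adp_c = -60.000000,
  amp_c = -67.382488,
  pi_c = -15.000000,
  nad_c = 0.000000,
  nadh_c = -9.382488,
  h_c = 0.000000,
  h2o_c = 1.617512,
  co2_c = 39.882488,
  hco3_c = 41.500000,
  gln_c = -51.617512,
  glu_c = -20.000000,
  cys_c = -15.000000,
  gly_c = -15.000000,
  gsh_c = 44.764977,
  ado_c = -20.000000,
  hpx_c = 33.235023,
  xan_c = 8.235023,
  ura_c = -16.764977,
  rib_c = -20.000000,
  nh3_c = -10.000000,
  accoa_c = 61.382488,
  coa_c = 0.000000,
  mcoa_c = 160.264977,
  but_c = 257.000000,
  mev_c = 362.000000,
  o2_c = 0.000000,
  o2s_c = 23.308756,
  hbuf_c = 0.000000,
  buf_c = 0.000000,
  o2_m = 0.000000,
  o2s_m = 23.308756,
  h2o2_m = 26.617512,
  gsh_m = 44.764977,
  gssg_m = -83.087558
)
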