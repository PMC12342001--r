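## The reduced liver network: a deterministic, thermodynamically
## self-consistent fixture spanning every pathway the perfusion analysis
## touches -- lumped glycolysis, pyruvate oxidation (Krebs) plus oxidative
## phosphorylation, purine degradation with superoxide release, the
## superoxide dismutase / catalase / glutathione peroxidase redox chemistry,
## glutathione synthesis and transport, the committed (irreversible)
## malonyl-CoA step with a lumped fatty-acid synthesis, mevalonate synthesis
## as the bile proxy, the adenylate pool, and CO2/bicarbonate buffering for
## pH.  Macro-scale reactions exchange protons with the imidazole-like
## buffer pair (hbuf/buf) -- the biochemical convention that reactions see
## buffered protons -- while the free proton species (the pH readout, the
## dismutation substrate and the protonation equilibria) stays a trace pool.
## Three compartments: extracellular (e), cytosol (c), mitochondrion (m);
## mitochondrial reactions draw on pooled cytosolic cofactors (a documented
## lumping).  Formation values are the frozen fixture in thermo-fixture.R.

.liverSpeciesDef <- function() {
  ## id, name, formula, charge, compartment
  def <- rbind(
    c("glc_e",  "glucose",               "C6H12O6",        0, "e"),
    c("lac_e",  "lactate",               "C3H6O3",         0, "e"),
    c("gsh_e",  "glutathione",           "C10H18N3O6S",    1, "e"),
    c("ado_e",  "adenosine",             "C10H13N5O4",     0, "e"),
    c("o2_e",   "oxygen",                "O2",             0, "e"),
    c("hco3_e", "bicarbonate",           "CHO3",          -1, "e"),
    c("co2_e",  "carbon dioxide",        "CO2",            0, "e"),
    c("gln_e",  "glutamine",             "C5H10N2O3",      0, "e"),
    c("ser_e",  "L-serine",              "C3H7NO3",        0, "e"),
    c("gly_e",  "glycine",               "C2H5NO2",        0, "e"),
    c("ala_e",  "L-alanine",             "C3H7NO2",        0, "e"),
    c("arg_e",  "L-arginine",            "C6H14N4O2",      0, "e"),
    c("asp_e",  "L-aspartate",           "C4H7NO4",        0, "e"),
    c("cys_e",  "L-cysteine",            "C3H7NO2S",       0, "e"),
    c("h2o_e",  "water",                 "H2O",            0, "e"),
    c("glc_c",  "glucose",               "C6H12O6",        0, "c"),
    c("pyr_c",  "pyruvate",              "C3H4O3",         0, "c"),
    c("lac_c",  "lactate",               "C3H6O3",         0, "c"),
    c("atp_c",  "ATP",                   "C10H16N5O13P3",  0, "c"),
    c("adp_c",  "ADP",                   "C10H15N5O10P2",  0, "c"),
    c("amp_c",  "AMP",                   "C10H14N5O7P",    0, "c"),
    c("pi_c",   "orthophosphate",        "H3PO4",          0, "c"),
    c("nad_c",  "NAD+",                  "C21H27N7O14P2",  1, "c"),
    c("nadh_c", "NADH",                  "C21H28N7O14P2",  0, "c"),
    c("h_c",    "proton",                "H",              1, "c"),
    c("h2o_c",  "water",                 "H2O",            0, "c"),
    c("co2_c",  "carbon dioxide",        "CO2",            0, "c"),
    c("hco3_c", "bicarbonate",           "CHO3",          -1, "c"),
    c("gln_c",  "glutamine",             "C5H10N2O3",      0, "c"),
    c("glu_c",  "glutamate",             "C5H9NO4",        0, "c"),
    c("cys_c",  "L-cysteine",            "C3H7NO2S",       0, "c"),
    c("gly_c",  "glycine",               "C2H5NO2",        0, "c"),
    c("gsh_c",  "glutathione",           "C10H18N3O6S",    1, "c"),
    c("ado_c",  "adenosine",             "C10H13N5O4",     0, "c"),
    c("hpx_c",  "hypoxanthine",          "C5H4N4O",        0, "c"),
    c("xan_c",  "xanthine",              "C5H4N4O2",       0, "c"),
    c("ura_c",  "urate",                 "C5H4N4O3",       0, "c"),
    c("rib_c",  "ribose",                "C5H10O5",        0, "c"),
    c("nh3_c",  "ammonia",               "NH3",            0, "c"),
    c("accoa_c","acetyl-CoA",            "C23H38N7O17P3S", 0, "c"),
    c("coa_c",  "coenzyme A",            "C21H36N7O16P3S", 0, "c"),
    c("mcoa_c", "malonyl-CoA",           "C24H38N7O19P3S", 0, "c"),
    c("but_c",  "butyrate",              "C4H8O2",         0, "c"),
    c("mev_c",  "mevalonate",            "C6H12O4",        0, "c"),
    c("o2_c",   "oxygen",                "O2",             0, "c"),
    c("o2s_c",  "superoxide",            "O2",            -1, "c"),
    c("hbuf_c", "protonated buffer",     "C3H5N2",         1, "c"),
    c("buf_c",  "buffer base",           "C3H4N2",         0, "c"),
    c("o2_m",   "oxygen",                "O2",             0, "m"),
    c("o2s_m",  "superoxide",            "O2",            -1, "m"),
    c("h2o2_m", "hydrogen peroxide",     "H2O2",           0, "m"),
    c("gsh_m",  "glutathione",           "C10H18N3O6S",    1, "m"),
    c("gssg_m", "glutathione disulfide", "C20H34N6O12S2",  2, "m")
  )
  data.frame(
    id = def[, 1], name = def[, 2], formula = def[, 3],
    charge = as.numeric(def[, 4]), compartment = def[, 5],
    stringsAsFactors = FALSE
  )
}

.liverReactionsDef <- function() {
  ## id, enzyme, node, irreversible, transport, equation
  rbind(
    c("R_GLY", "glycolysis (lumped; EC 2.7.1.1 ... 2.7.1.40)", "gly", TRUE, FALSE,
      "glc_c + 2 adp_c + 2 pi_c + 2 nad_c + 2 buf_c = 2 pyr_c + 2 atp_c + 2 nadh_c + 2 hbuf_c + 2 h2o_c"),
    c("R_LDH", "lactate dehydrogenase (EC 1.1.1.27)", "gly", FALSE, FALSE,
      "pyr_c + nadh_c + hbuf_c = lac_c + nad_c + buf_c"),
    c("T_GLC", "", "gly", FALSE, TRUE, "glc_e = glc_c"),
    c("T_LAC", "", "gly", FALSE, TRUE, "lac_c = lac_e"),
    c("R_PDH", "pyruvate dehydrogenase (EC 1.2.4.1)", "krb", TRUE, FALSE,
      "pyr_c + coa_c + nad_c + buf_c = accoa_c + co2_c + nadh_c + hbuf_c"),
    c("R_TCA", "Krebs cycle (lumped; EC 1.2.4.1 ... 6.2.1.4)", "krb", TRUE, FALSE,
      "pyr_c + 5 nad_c + 2 h2o_c + adp_c + pi_c + 5 buf_c = 3 co2_c + 5 nadh_c + 5 hbuf_c + atp_c"),
    c("R_OXP", "oxidative phosphorylation (lumped ETC + ATP synthase)", "oxp", TRUE, FALSE,
      "2 nadh_c + 2 hbuf_c + o2_m + 5 adp_c + 5 pi_c = 2 nad_c + 2 buf_c + 7 h2o_c + 5 atp_c"),
    c("R_LEAK", "ETC electron leak to superoxide", "oxp", TRUE, FALSE,
      "nadh_c + 2 o2_m + buf_c = nad_c + 2 o2s_m + hbuf_c"),
    c("T_O2M", "", "oxp", FALSE, TRUE, "o2_c = o2_m"),
    c("R_ADA", "adenosine deaminase + nucleosidase (lumped; EC 3.5.4.4)", "pur", FALSE, FALSE,
      "ado_c + 2 h2o_c = hpx_c + rib_c + nh3_c"),
    c("R_XO1", "xanthine oxidase (EC 1.17.3.2)", "pur", TRUE, FALSE,
      "hpx_c + h2o_c + 2 o2_c + 2 buf_c = xan_c + 2 o2s_c + 2 hbuf_c"),
    c("R_XO2", "xanthine oxidase (EC 1.17.3.2)", "pur", TRUE, FALSE,
      "xan_c + h2o_c + 2 o2_c + 2 buf_c = ura_c + 2 o2s_c + 2 hbuf_c"),
    c("T_ADO", "", "pur", FALSE, TRUE, "ado_e = ado_c"),
    c("T_O2C", "", "pur", FALSE, TRUE, "o2_e = o2_c"),
    c("T_O2S", "", "pur", FALSE, TRUE, "o2s_c = o2s_m"),
    c("R_SOD", "superoxide dismutase (EC 1.15.1.1)", "ros", TRUE, FALSE,
      "2 o2s_m + 2 h_c = h2o2_m + o2_m"),
    c("R_CAT", "catalase (EC 1.11.1.6)", "ros", TRUE, FALSE,
      "2 h2o2_m = 2 h2o_c + o2_m"),
    c("R_GPX", "glutathione peroxidase (EC 1.11.1.9)", "ros", TRUE, FALSE,
      "2 gsh_m + h2o2_m = gssg_m + 2 h2o_c"),
    c("R_GLS", "glutaminase (EC 3.5.1.2)", "gsx", FALSE, FALSE,
      "gln_c + h2o_c = glu_c + nh3_c"),
    c("R_GSS", "glutathione synthesis (lumped; EC 6.3.2.2 + 6.3.2.3)", "gsx", FALSE, FALSE,
      "glu_c + cys_c + gly_c + hbuf_c + 2 atp_c = gsh_c + 2 adp_c + 2 pi_c + buf_c"),
    c("T_GSHE", "", "gsx", FALSE, TRUE, "gsh_e = gsh_c"),
    c("T_GSHM", "", "gsx", TRUE, TRUE, "gsh_c = gsh_m"),
    c("T_GLN", "", "gsx", FALSE, TRUE, "gln_e = gln_c"),
    c("T_CYS", "", "gsx", FALSE, TRUE, "cys_e = cys_c"),
    c("T_GLY", "", "gsx", FALSE, TRUE, "gly_e = gly_c"),
    c("R_ACC", "acetyl-CoA carboxylase (EC 6.4.1.2, committed step)", "lip", TRUE, FALSE,
      "accoa_c + co2_c + atp_c + h2o_c = mcoa_c + adp_c + pi_c"),
    c("R_FAS", "fatty-acid synthesis (lumped; EC 2.3.1.85)", "lip", TRUE, FALSE,
      "2 mcoa_c + 2 nadh_c + 2 hbuf_c = but_c + 2 co2_c + 2 coa_c + 2 nad_c + 2 buf_c"),
    c("R_MEV", "mevalonate synthesis (lumped; EC 2.3.3.10 + 1.1.1.34)", "lip", TRUE, FALSE,
      "3 accoa_c + 2 nadh_c + 2 hbuf_c + h2o_c = mev_c + 3 coa_c + 2 nad_c + 2 buf_c"),
    c("R_BUF_gly", "proton buffer (lumped protonation equilibria)", "gly", FALSE, FALSE,
      "hbuf_c = buf_c + h_c"),
    c("R_BUF_krb", "proton buffer (lumped protonation equilibria)", "krb", FALSE, FALSE,
      "hbuf_c = buf_c + h_c"),
    c("R_BUF_oxp", "proton buffer (lumped protonation equilibria)", "oxp", FALSE, FALSE,
      "hbuf_c = buf_c + h_c"),
    c("R_BUF_pur", "proton buffer (lumped protonation equilibria)", "pur", FALSE, FALSE,
      "hbuf_c = buf_c + h_c"),
    c("R_BUF_ros", "proton buffer (lumped protonation equilibria)", "ros", FALSE, FALSE,
      "hbuf_c = buf_c + h_c"),
    c("R_BUF_gsx", "proton buffer (lumped protonation equilibria)", "gsx", FALSE, FALSE,
      "hbuf_c = buf_c + h_c"),
    c("R_BUF_lip", "proton buffer (lumped protonation equilibria)", "lip", FALSE, FALSE,
      "hbuf_c = buf_c + h_c"),
    c("R_BUF_adn", "proton buffer (lumped protonation equilibria)", "adn", FALSE, FALSE,
      "hbuf_c = buf_c + h_c"),
    c("R_ADK", "adenylate kinase (EC 2.7.4.3)", "adn", FALSE, FALSE,
      "2 adp_c = atp_c + amp_c"),
    c("R_MNT", "maintenance ATP load (lumped ATPases)", "adn", TRUE, FALSE,
      "atp_c + h2o_c = adp_c + pi_c"),
    c("R_CAH", "carbonic anhydrase (EC 4.2.1.1)", "adn", FALSE, FALSE,
      "co2_c + h2o_c = hco3_c + h_c"),
    c("T_HCO3", "", "adn", FALSE, TRUE, "hco3_e = hco3_c"),
    c("T_CO2", "", "adn", FALSE, TRUE, "co2_c = co2_e"),
    c("T_H2O", "", "adn", FALSE, TRUE, "h2o_e = h2o_c")
  )
}

#' Build the reduced liver network fixture
#'
#' Deterministic: same object on every call.  All reactions are element- and
#' charge-balanced; formation values are the frozen fixture solved so that
#' the glutathione-peroxidase reaction enthalpy is exactly -196 kJ/mol, ATP
#' hydrolysis is about -30.5 kJ/mol, and every pathway runs in its
#' physiological direction at 310 K.
#'
#' @return a [MetabolicNetwork-class]
#' @export
buildReducedLiverNetwork <- function() {
  sp <- .liverSpeciesDef()
  sp$dGf0 <- unname(.LIVER_DGF[sp$id])
  sp$dHf0 <- unname(.LIVER_DHF[sp$id])
  rdef <- .liverReactionsDef()
  rx <- lapply(seq_len(nrow(rdef)), function(i) {
    new("Reaction",
      id = rdef[i, 1], enzyme = rdef[i, 2], node = rdef[i, 3],
      irreversible = as.logical(rdef[i, 4]), transport = as.logical(rdef[i, 5]),
      stoich = parseEquation(rdef[i, 6])
    )
  })
  metabolicNetwork(sp, rx)
}

#' Initial (pre-flush) intracellular state of the liver model
#'
#' Physiologically plausible amounts (nmol/cell) at 310.15 K: adenylate pool
#' near 3 mM ATP with energy charge about 0.85, NAD mostly oxidised, cytosolic
#' pH near 7.4 through the proton/bicarbonate pair, a small residual of
#' dissolved oxygen that feeds xanthine oxidase during hypoxia, and trace ROS.
#'
#' @param net the reduced liver network
#' @param volume intracellular per-cell volume, nmol/(cell mM)
#' @return a [SystemState-class]
#' @export
initialLiverState <- function(net, volume = defaultVolume()) {
  a <- setNames(numeric(nrow(net@species)), net@species$id)
  mM <- function(x) x * volume # concentration -> amount
  a["glc_c"] <- mM(2)
  a["pyr_c"] <- mM(0.1)
  a["lac_c"] <- mM(0.8)
  a["atp_c"] <- mM(3.0)
  a["adp_c"] <- mM(2)
  a["amp_c"] <- mM(0.5)
  a["pi_c"]  <- mM(8)
  a["nad_c"] <- mM(3)
  a["nadh_c"] <- mM(0.3)
  a["h_c"]   <- mM(10^(-7.4) * 1000) # pH 7.4
  a["h2o_c"] <- 5.54
  a["hbuf_c"] <- 8
  a["buf_c"] <- 8
  a["co2_c"] <- mM(1.2)
  a["hco3_c"] <- mM(24)
  a["gln_c"] <- mM(0.5)
  a["glu_c"] <- mM(2)
  a["cys_c"] <- mM(0.1)
  a["gly_c"] <- mM(0.3)
  a["gsh_c"] <- mM(4)
  a["gsh_m"] <- mM(0.5)
  a["gssg_m"] <- 5e-5
  a["ado_c"] <- mM(0.01)
  a["coa_c"] <- mM(0.1)
  a["accoa_c"] <- mM(0.05)
  a["o2_c"] <- mM(0.05)
  a["o2_m"] <- mM(0.05)
  a["o2s_c"] <- 1e-12
  a["o2s_m"] <- 1e-12
  a["h2o2_m"] <- 1e-9
  ## extracellular space starts as interstitial fluid; the protocol flushes it
  a["glc_e"] <- mM(5)
  a["h2o_e"] <- 5.54
  a["hco3_e"] <- mM(24)
  a["co2_e"] <- mM(1.2)
  a["o2_e"] <- mM(0.1)
  new("SystemState", amounts = a, temperature = 310.15, time = 0)
}

#' Default intracellular per-cell volume, nmol/(cell mM)
#'
#' The factor implied by the perfusate table (amount / molarity of the
#' internally consistent glutamine row), used for all concentration <->
#' amount conversions in the simulator.
#' @export
defaultVolume <- function() 0.2221 / 1.9990
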