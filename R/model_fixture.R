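# curated core network of xylose/polyol metabolism in an oleaginous yeast
#
# Scope: xylose assimilation (XR/XDH/XK), both arabitol isoform routes with
# the artificial pool, non-oxidative and oxidative PPP, phosphoketolase +
# phosphate transacetylase, the glycolytic trunk, the pyruvate node (PYC,
# PDC, PDH, mitochondrial carrier), acetyl-CoA sources (ACS, ACL, PTA), TCA
# cycle, glyoxylate shunt, malic enzyme, glutamate/glutamine assimilation,
# lumped C18:1 fatty-acid synthesis and beta-oxidation, mevalonate-route
# carotenoid lumps for the four pigments, an oxidative-phosphorylation lump
# with fixed P/O, polymerisation reactions for glucan and protein, and
# biomass/NGAM pseudo-reactions.
#
# Bookkeeping conventions: neutral (fully protonated) formulas throughout,
# so charge balancing is trivial and redox cofactors carry 2 H per reduced
# equivalent (NADH = NAD + H2); FADH2 is a bookkeeping species of formula
# H2 feeding the FADH2-specific oxphos lump. Gene ids with the RTSYN_
# prefix are synthetic placeholders for enzymes whose R. toruloides locus
# tags are not tracked here.

core_metabolite_table <- function() {
  m <- function(id, name, comp, formula) {
    data.frame(id = id, name = name, compartment = comp, formula = formula,
               charge = 0, stringsAsFactors = FALSE)
  }
  rbind(
    m("xyl_c", "D-xylose", "c", "C5H10O5"),
    m("xlt_c", "xylitol", "c", "C5H12O5"),
    m("xul_c", "D-xylulose", "c", "C5H10O5"),
    m("x5p_c", "D-xylulose 5-phosphate", "c", "C5H11O8P"),
    m("ru5p_c", "D-ribulose 5-phosphate", "c", "C5H11O8P"),
    m("r5p_c", "D-ribose 5-phosphate", "c", "C5H11O8P"),
    m("s7p_c", "sedoheptulose 7-phosphate", "c", "C7H15O10P"),
    m("e4p_c", "D-erythrose 4-phosphate", "c", "C4H9O7P"),
    m("g6p_c", "D-glucose 6-phosphate", "c", "C6H13O9P"),
    m("pg6_c", "6-phospho-D-gluconate", "c", "C6H13O10P"),
    m("f6p_c", "D-fructose 6-phosphate", "c", "C6H13O9P"),
    m("fbp_c", "D-fructose 1,6-bisphosphate", "c", "C6H14O12P2"),
    m("dhap_c", "dihydroxyacetone phosphate", "c", "C3H7O6P"),
    m("gap_c", "D-glyceraldehyde 3-phosphate", "c", "C3H7O6P"),
    m("bpg13_c", "1,3-bisphospho-D-glycerate", "c", "C3H8O10P2"),
    m("pg3_c", "3-phospho-D-glycerate", "c", "C3H7O7P"),
    m("pg2_c", "2-phospho-D-glycerate", "c", "C3H7O7P"),
    m("pep_c", "phosphoenolpyruvate", "c", "C3H5O6P"),
    m("pyr_c", "pyruvate", "c", "C3H4O3"),
    m("acp_c", "acetyl phosphate", "c", "C2H5O5P"),
    m("ac_c", "acetate", "c", "C2H4O2"),
    m("acald_c", "acetaldehyde", "c", "C2H4O"),
    m("accoa_c", "acetyl-CoA", "c", "C23H38N7O17P3S"),
    m("coa_c", "coenzyme A", "c", "C21H36N7O16P3S"),
    m("oaa_c", "oxaloacetate", "c", "C4H4O5"),
    m("cit_c", "citrate", "c", "C6H8O7"),
    m("icit_c", "isocitrate", "c", "C6H8O7"),
    m("akg_c", "2-oxoglutarate", "c", "C5H6O5"),
    m("mal_c", "L-malate", "c", "C4H6O5"),
    m("succ_c", "succinate", "c", "C4H6O4"),
    m("glx_c", "glyoxylate", "c", "C2H2O3"),
    m("glu_c", "L-glutamate", "c", "C5H9NO4"),
    m("gln_c", "L-glutamine", "c", "C5H10N2O3"),
    m("nh3_c", "ammonia", "c", "H3N"),
    m("atp_c", "ATP", "c", "C10H16N5O13P3"),
    m("adp_c", "ADP", "c", "C10H15N5O10P2"),
    m("amp_c", "AMP", "c", "C10H14N5O7P"),
    m("ppi_c", "diphosphate", "c", "H4P2O7"),
    m("pi_c", "phosphate", "c", "H3PO4"),
    m("nad_c", "NAD+", "c", "C21H27N7O14P2"),
    m("nadh_c", "NADH", "c", "C21H29N7O14P2"),
    m("nadp_c", "NADP+", "c", "C21H28N7O17P3"),
    m("nadph_c", "NADPH", "c", "C21H30N7O17P3"),
    m("h2o_c", "water", "c", "H2O"),
    m("co2_c", "carbon dioxide", "c", "CO2"),
    m("o2_c", "oxygen", "c", "O2"),
    m("glc_c", "D-glucose", "c", "C6H12O6"),
    m("glyc_c", "glycerol", "c", "C3H8O3"),
    m("glyc3p_c", "sn-glycerol 3-phosphate", "c", "C3H9O6P"),
    m("olea_c", "oleate (average fatty acid)", "c", "C18H34O2"),
    m("oleacoa_c", "oleoyl-CoA (average acyl-CoA)", "c", "C39H68N7O17P3S"),
    m("tag_c", "triacylglyceride (average)", "c", "C57H104O6"),
    m("glucan_c", "glucan unit (carbohydrate)", "c", "C6H10O5"),
    m("protein_c", "protein residue (average)", "c", "C5H7.2N1.2O2.8"),
    m("bcaro_c", "beta-carotene", "c", "C40H56"),
    m("gcaro_c", "gamma-carotene", "c", "C40H56"),
    m("torulene_c", "torulene", "c", "C40H54"),
    m("torularhodin_c", "torularhodin", "c", "C40H52O2"),
    m("pyr_m", "pyruvate", "m", "C3H4O3"),
    m("accoa_m", "acetyl-CoA", "m", "C23H38N7O17P3S"),
    m("coa_m", "coenzyme A", "m", "C21H36N7O16P3S"),
    m("oaa_m", "oxaloacetate", "m", "C4H4O5"),
    m("cit_m", "citrate", "m", "C6H8O7"),
    m("icit_m", "isocitrate", "m", "C6H8O7"),
    m("akg_m", "2-oxoglutarate", "m", "C5H6O5"),
    m("succoa_m", "succinyl-CoA", "m", "C25H40N7O19P3S"),
    m("succ_m", "succinate", "m", "C4H6O4"),
    m("fum_m", "fumarate", "m", "C4H4O4"),
    m("mal_m", "L-malate", "m", "C4H6O5"),
    m("nad_m", "NAD+", "m", "C21H27N7O14P2"),
    m("nadh_m", "NADH", "m", "C21H29N7O14P2"),
    m("fadh2_m", "FADH2 (bookkeeping reduced equivalent)", "m", "H2"),
    m("atp_m", "ATP", "m", "C10H16N5O13P3"),
    m("adp_m", "ADP", "m", "C10H15N5O10P2"),
    m("pi_m", "phosphate", "m", "H3PO4"),
    m("h2o_m", "water", "m", "H2O"),
    m("co2_m", "carbon dioxide", "m", "CO2"),
    m("o2_m", "oxygen", "m", "O2"),
    m("xyl_e", "D-xylose", "e", "C5H10O5"),
    m("xlt_e", "xylitol", "e", "C5H12O5"),
    m("glc_e", "D-glucose", "e", "C6H12O6"),
    m("glyc_e", "glycerol", "e", "C3H8O3"),
    m("nh3_e", "ammonia", "e", "H3N"),
    m("o2_e", "oxygen", "e", "O2"),
    m("co2_e", "carbon dioxide", "e", "CO2"),
    m("h2o_e", "water", "e", "H2O"),
    m("biomass_e", "biomass", "e", "")
  )
}

core_reaction_list <- function() {
  r <- function(id, name, mets, lb = 0, ub = 1000, subsystem = "",
                genes = character(0), pseudo = FALSE) {
    list(id = id, name = name, mets = mets, lb = lb, ub = ub,
         subsystem = subsystem, genes = genes, pseudo = pseudo)
  }
  rev <- -1000
  list(
    # exchanges (met_e ->, uptake negative)
    r("EX_xyl", "xylose exchange", c(xyl_e = -1), subsystem = "Exchange"),
    r("EX_xlt", "xylitol exchange", c(xlt_e = -1), subsystem = "Exchange"),
    r("EX_glc", "glucose exchange", c(glc_e = -1), subsystem = "Exchange"),
    r("EX_glyc", "glycerol exchange", c(glyc_e = -1), subsystem = "Exchange"),
    r("EX_nh3", "ammonia exchange", c(nh3_e = -1), lb = rev, subsystem = "Exchange"),
    r("EX_o2", "oxygen exchange", c(o2_e = -1), lb = rev, subsystem = "Exchange"),
    r("EX_co2", "CO2 exchange", c(co2_e = -1), lb = rev, subsystem = "Exchange"),
    r("EX_h2o", "water exchange", c(h2o_e = -1), lb = rev, subsystem = "Exchange"),
    r("EX_biomass", "biomass exchange", c(biomass_e = -1), subsystem = "Exchange"),
    # transport
    r("XYLt", "xylose uptake", c(xyl_e = -1, xyl_c = 1), subsystem = "Transport"),
    r("XLTt", "xylitol transport", c(xlt_c = -1, xlt_e = 1), lb = rev,
      subsystem = "Transport"),
    r("GLCt", "glucose uptake", c(glc_e = -1, glc_c = 1), subsystem = "Transport"),
    r("GLYCt", "glycerol transport", c(glyc_e = -1, glyc_c = 1), lb = rev,
      subsystem = "Transport"),
    r("NH3t", "ammonia uptake", c(nh3_e = -1, nh3_c = 1), subsystem = "Transport"),
    r("O2t", "oxygen uptake", c(o2_e = -1, o2_c = 1), subsystem = "Transport"),
    r("O2tm", "oxygen diffusion (mitochondrial)", c(o2_c = -1, o2_m = 1),
      subsystem = "Transport"),
    r("CO2t", "CO2 export", c(co2_c = -1, co2_e = 1), lb = rev,
      subsystem = "Transport"),
    r("CO2tm", "CO2 diffusion (mitochondrial)", c(co2_m = -1, co2_c = 1),
      lb = rev, subsystem = "Transport"),
    r("H2Ot", "water transport", c(h2o_c = -1, h2o_e = 1), lb = rev,
      subsystem = "Transport"),
    r("H2Otm", "water transport (mitochondrial)", c(h2o_c = -1, h2o_m = 1),
      lb = rev, subsystem = "Transport"),
    r("PYRtm", "mitochondrial pyruvate carrier", c(pyr_c = -1, pyr_m = 1),
      subsystem = "Transport", genes = "RTSYN_MPC1"),
    r("CITtm", "citrate transport", c(cit_m = -1, cit_c = 1), lb = rev,
      subsystem = "Transport"),
    r("MALtm", "malate transport", c(mal_c = -1, mal_m = 1), lb = rev,
      subsystem = "Transport"),
    r("AKGtm", "2-oxoglutarate transport", c(akg_m = -1, akg_c = 1), lb = rev,
      subsystem = "Transport"),
    r("OAAtm", "oxaloacetate transport", c(oaa_c = -1, oaa_m = 1), lb = rev,
      subsystem = "Transport"),
    r("SUCCtm", "succinate transport", c(succ_c = -1, succ_m = 1), lb = rev,
      subsystem = "Transport"),
    r("ATPtm", "ADP/ATP translocase",
      c(atp_m = -1, adp_c = -1, atp_c = 1, adp_m = 1), lb = rev,
      subsystem = "Transport"),
    r("PItm", "phosphate transport", c(pi_c = -1, pi_m = 1), lb = rev,
      subsystem = "Transport"),
    r("NADHsh", "cytosolic-mitochondrial NADH shuttle (lumped)",
      c(nadh_c = -1, nad_m = -1, nad_c = 1, nadh_m = 1),
      subsystem = "Transport"),
    # xylose assimilation
    r("XR", "xylose reductase (NADPH)",
      c(xyl_c = -1, nadph_c = -1, xlt_c = 1, nadp_c = 1),
      subsystem = "Xylose assimilation", genes = "RTSYN_XYL1"),
    r("XDH", "xylitol dehydrogenase",
      c(xlt_c = -1, nad_c = -1, xul_c = 1, nadh_c = 1), lb = rev,
      subsystem = "Xylose assimilation", genes = "RTSYN_XYL2"),
    r("XK", "xylulokinase",
      c(xul_c = -1, atp_c = -1, x5p_c = 1, adp_c = 1),
      subsystem = "Xylose assimilation", genes = "RTSYN_XKS1"),
    # pentose phosphate pathway
    r("ZWF", "glucose-6-phosphate dehydrogenase (lumped with lactonase)",
      c(g6p_c = -1, nadp_c = -1, h2o_c = -1, pg6_c = 1, nadph_c = 1),
      subsystem = "Pentose phosphate pathway (oxidative)",
      genes = "RTSYN_ZWF1"),
    r("GND", "6-phosphogluconate dehydrogenase",
      c(pg6_c = -1, nadp_c = -1, ru5p_c = 1, co2_c = 1, nadph_c = 1),
      subsystem = "Pentose phosphate pathway (oxidative)",
      genes = "RHTO_02788"),
    r("RPE", "ribulose-5-phosphate 3-epimerase",
      c(ru5p_c = -1, x5p_c = 1), lb = rev,
      subsystem = "Pentose phosphate pathway (non-oxidative)"),
    r("RPI", "ribose-5-phosphate isomerase",
      c(ru5p_c = -1, r5p_c = 1), lb = rev,
      subsystem = "Pentose phosphate pathway (non-oxidative)"),
    r("TKT1", "transketolase (X5P + R5P)",
      c(x5p_c = -1, r5p_c = -1, s7p_c = 1, gap_c = 1), lb = rev,
      subsystem = "Pentose phosphate pathway (non-oxidative)",
      genes = "RHTO_03248"),
    r("TAL", "transaldolase",
      c(s7p_c = -1, gap_c = -1, e4p_c = 1, f6p_c = 1), lb = rev,
      subsystem = "Pentose phosphate pathway (non-oxidative)"),
    r("TKT2", "transketolase (X5P + E4P)",
      c(x5p_c = -1, e4p_c = -1, f6p_c = 1, gap_c = 1), lb = rev,
      subsystem = "Pentose phosphate pathway (non-oxidative)",
      genes = "RHTO_03248"),
    r("PK", "phosphoketolase",
      c(x5p_c = -1, pi_c = -1, acp_c = 1, gap_c = 1, h2o_c = 1),
      subsystem = "Phosphoketolase pathway", genes = "RHTO_04463"),
    r("PTA", "phosphate transacetylase",
      c(acp_c = -1, coa_c = -1, accoa_c = 1, pi_c = 1), lb = rev,
      subsystem = "Phosphoketolase pathway", genes = "RTSYN_PTA1"),
    # glycolysis trunk
    r("PGI", "glucose-6-phosphate isomerase", c(g6p_c = -1, f6p_c = 1),
      lb = rev, subsystem = "Glycolysis"),
    r("PFK", "phosphofructokinase",
      c(f6p_c = -1, atp_c = -1, fbp_c = 1, adp_c = 1),
      subsystem = "Glycolysis"),
    r("FBA", "fructose-bisphosphate aldolase",
      c(fbp_c = -1, dhap_c = 1, gap_c = 1), lb = rev,
      subsystem = "Glycolysis"),
    r("TPI", "triose-phosphate isomerase", c(dhap_c = -1, gap_c = 1),
      lb = rev, subsystem = "Glycolysis"),
    r("GAPDH", "glyceraldehyde-3-phosphate dehydrogenase",
      c(gap_c = -1, nad_c = -1, pi_c = -1, bpg13_c = 1, nadh_c = 1),
      lb = rev, subsystem = "Glycolysis"),
    r("PGK", "phosphoglycerate kinase",
      c(bpg13_c = -1, adp_c = -1, pg3_c = 1, atp_c = 1), lb = rev,
      subsystem = "Glycolysis"),
    r("PGM", "phosphoglycerate mutase", c(pg3_c = -1, pg2_c = 1), lb = rev,
      subsystem = "Glycolysis"),
    r("ENO", "enolase", c(pg2_c = -1, pep_c = 1, h2o_c = 1), lb = rev,
      subsystem = "Glycolysis"),
    r("PYK", "pyruvate kinase",
      c(pep_c = -1, adp_c = -1, pyr_c = 1, atp_c = 1),
      subsystem = "Glycolysis", genes = "RTSYN_PYK1"),
    r("HXK", "hexokinase", c(glc_c = -1, atp_c = -1, g6p_c = 1, adp_c = 1),
      subsystem = "Glycolysis"),
    # pyruvate node and acetyl-CoA sources
    r("PDC", "pyruvate decarboxylase", c(pyr_c = -1, acald_c = 1, co2_c = 1),
      subsystem = "Pyruvate metabolism", genes = "RTSYN_PDC1"),
    r("ALD", "acetaldehyde dehydrogenase (NADP)",
      c(acald_c = -1, nadp_c = -1, h2o_c = -1, ac_c = 1, nadph_c = 1),
      subsystem = "Pyruvate metabolism", genes = "RTSYN_ALD6"),
    r("ACS", "acetyl-CoA synthetase",
      c(ac_c = -1, coa_c = -1, atp_c = -1, accoa_c = 1, amp_c = 1, ppi_c = 1),
      subsystem = "Pyruvate metabolism", genes = "RHTO_08027"),
    r("PPA", "inorganic pyrophosphatase",
      c(ppi_c = -1, h2o_c = -1, pi_c = 2), subsystem = "Pyruvate metabolism"),
    r("ADK", "adenylate kinase", c(atp_c = -1, amp_c = -1, adp_c = 2),
      lb = rev, subsystem = "Pyruvate metabolism"),
    r("PYC", "pyruvate carboxylase",
      c(pyr_c = -1, co2_c = -1, atp_c = -1, h2o_c = -1, oaa_c = 1,
        adp_c = 1, pi_c = 1),
      subsystem = "Anaplerosis", genes = "RTSYN_PYC1"),
    r("PDH", "pyruvate dehydrogenase",
      c(pyr_m = -1, coa_m = -1, nad_m = -1, accoa_m = 1, co2_m = 1,
        nadh_m = 1),
      subsystem = "Pyruvate metabolism", genes = "RTSYN_PDA1"),
    r("ACL", "ATP-citrate lyase",
      c(cit_c = -1, atp_c = -1, coa_c = -1, accoa_c = 1, oaa_c = 1,
        adp_c = 1, pi_c = 1),
      subsystem = "Acetyl-CoA metabolism", genes = "RHTO_03915"),
    # TCA cycle
    r("CIT", "citrate synthase",
      c(accoa_m = -1, oaa_m = -1, h2o_m = -1, cit_m = 1, coa_m = 1),
      subsystem = "TCA cycle", genes = "RHTO_06406"),
    r("ACO", "aconitase", c(cit_m = -1, icit_m = 1), lb = rev,
      subsystem = "TCA cycle"),
    r("ACOc", "aconitase (cytosolic)", c(cit_c = -1, icit_c = 1), lb = rev,
      subsystem = "TCA cycle"),
    r("IDH", "isocitrate dehydrogenase",
      c(icit_m = -1, nad_m = -1, akg_m = 1, co2_m = 1, nadh_m = 1),
      subsystem = "TCA cycle", genes = "RHTO_04315"),
    r("KGD", "2-oxoglutarate dehydrogenase",
      c(akg_m = -1, coa_m = -1, nad_m = -1, succoa_m = 1, co2_m = 1,
        nadh_m = 1),
      subsystem = "TCA cycle"),
    r("SCS", "succinyl-CoA synthetase",
      c(succoa_m = -1, adp_m = -1, pi_m = -1, succ_m = 1, atp_m = 1,
        coa_m = 1), lb = rev, subsystem = "TCA cycle"),
    r("SDH", "succinate dehydrogenase",
      c(succ_m = -1, fum_m = 1, fadh2_m = 1), subsystem = "TCA cycle"),
    r("FUM", "fumarase", c(fum_m = -1, h2o_m = -1, mal_m = 1), lb = rev,
      subsystem = "TCA cycle"),
    r("MDH", "malate dehydrogenase",
      c(mal_m = -1, nad_m = -1, oaa_m = 1, nadh_m = 1), lb = rev,
      subsystem = "TCA cycle", genes = "RHTO_04363"),
    r("MDHc", "malate dehydrogenase (cytosolic)",
      c(mal_c = -1, nad_c = -1, oaa_c = 1, nadh_c = 1), lb = rev,
      subsystem = "TCA cycle"),
    # glyoxylate shunt and malic enzyme
    r("ICL", "isocitrate lyase", c(icit_c = -1, succ_c = 1, glx_c = 1),
      subsystem = "Glyoxylate shunt"),
    r("MLS", "malate synthase",
      c(glx_c = -1, accoa_c = -1, h2o_c = -1, mal_c = 1, coa_c = 1),
      subsystem = "Glyoxylate shunt"),
    r("ME", "malic enzyme (NADP)",
      c(mal_c = -1, nadp_c = -1, pyr_c = 1, co2_c = 1, nadph_c = 1),
      subsystem = "Anaplerosis", genes = "RTSYN_MAE1"),
    # nitrogen assimilation
    r("GDH", "glutamate dehydrogenase (NADPH)",
      c(akg_c = -1, nh3_c = -1, nadph_c = -1, glu_c = 1, nadp_c = 1,
        h2o_c = 1),
      subsystem = "Nitrogen metabolism", genes = c("RHTO_04650", "RHTO_07718")),
    r("GLNS", "glutamine synthetase",
      c(glu_c = -1, nh3_c = -1, atp_c = -1, gln_c = 1, adp_c = 1, pi_c = 1),
      subsystem = "Nitrogen metabolism", genes = c("RHTO_00673", "RHTO_00401")),
    # oxidative phosphorylation lumps (fixed P/O: 1.5 per NADH, 1 per FADH2)
    r("OXPHOSn", "oxidative phosphorylation (NADH lump)",
      c(nadh_m = -1, o2_m = -0.5, adp_m = -1.5, pi_m = -1.5, nad_m = 1,
        atp_m = 1.5, h2o_m = 2.5),
      subsystem = "Oxidative phosphorylation"),
    r("OXPHOSf", "oxidative phosphorylation (FADH2 lump)",
      c(fadh2_m = -1, o2_m = -0.5, adp_m = -1, pi_m = -1, atp_m = 1,
        h2o_m = 2),
      subsystem = "Oxidative phosphorylation"),
    # lipid metabolism (lumped around the average C18:1 acyl chain)
    r("G3PD", "glycerol-3-phosphate dehydrogenase",
      c(dhap_c = -1, nadh_c = -1, glyc3p_c = 1, nad_c = 1), lb = rev,
      subsystem = "Lipid metabolism"),
    r("GLYK", "glycerol kinase",
      c(glyc_c = -1, atp_c = -1, glyc3p_c = 1, adp_c = 1),
      subsystem = "Lipid metabolism"),
    r("FAS", "fatty-acid synthesis lump (to oleoyl-CoA)",
      c(accoa_c = -9, nadph_c = -16, atp_c = -8, o2_c = -1, nadh_c = -1,
        oleacoa_c = 1, coa_c = 8, nadp_c = 16, adp_c = 8, pi_c = 8,
        nad_c = 1, h2o_c = 2),
      subsystem = "Lipid metabolism",
      genes = c("RHTO_02004", "RHTO_02032", "RHTO_02139")),
    r("TAGS", "triacylglyceride assembly",
      c(glyc3p_c = -1, oleacoa_c = -3, h2o_c = -1, tag_c = 1, coa_c = 3,
        pi_c = 1),
      subsystem = "Lipid metabolism"),
    r("LIPASE", "triacylglyceride lipase",
      c(tag_c = -1, h2o_c = -3, glyc_c = 1, olea_c = 3),
      subsystem = "Lipid metabolism"),
    r("FACS", "fatty-acyl-CoA synthetase",
      c(olea_c = -1, coa_c = -1, atp_c = -1, oleacoa_c = 1, amp_c = 1,
        ppi_c = 1),
      subsystem = "Lipid metabolism"),
    r("BOX", "beta-oxidation lump (oleoyl-CoA)",
      c(oleacoa_c = -1, coa_c = -8, nad_c = -8, h2o_c = -8, accoa_c = 9,
        nadh_c = 8, fadh2_m = 7),
      subsystem = "Lipid metabolism", genes = "RTSYN_POX1"),
    # mevalonate-route carotenoid lumps
    r("CAROb", "beta-carotene synthesis lump",
      c(accoa_c = -24, nadph_c = -16, atp_c = -24, o2_c = -2, h2o_c = -12,
        bcaro_c = 1, co2_c = 8, coa_c = 24, nadp_c = 16, adp_c = 24,
        pi_c = 24),
      subsystem = "Carotenoid biosynthesis",
      genes = c("RHTO_02048", "RHTO_02305", "RHTO_04045", "RHTO_04602")),
    r("CAROg", "gamma-carotene synthesis lump",
      c(accoa_c = -24, nadph_c = -16, atp_c = -24, o2_c = -2, h2o_c = -12,
        gcaro_c = 1, co2_c = 8, coa_c = 24, nadp_c = 16, adp_c = 24,
        pi_c = 24),
      subsystem = "Carotenoid biosynthesis",
      genes = c("RHTO_02048", "RHTO_02305", "RHTO_04045", "RHTO_04602")),
    r("CAROt", "torulene synthesis lump",
      c(accoa_c = -24, nadph_c = -16, atp_c = -24, o2_c = -2.5, h2o_c = -11,
        torulene_c = 1, co2_c = 8, coa_c = 24, nadp_c = 16, adp_c = 24,
        pi_c = 24),
      subsystem = "Carotenoid biosynthesis",
      genes = c("RHTO_02048", "RHTO_02305", "RHTO_04045", "RHTO_04602")),
    r("CAROtr", "torularhodin synthesis lump",
      c(accoa_c = -24, nadph_c = -16, atp_c = -24, o2_c = -4, h2o_c = -10,
        torularhodin_c = 1, co2_c = 8, coa_c = 24, nadp_c = 16, adp_c = 24,
        pi_c = 24),
      subsystem = "Carotenoid biosynthesis",
      genes = c("RHTO_02048", "RHTO_02305", "RHTO_04045", "RHTO_04602")),
    # polymerisation
    r("GLUCANS", "glucan synthesis (carbohydrate lump)",
      c(g6p_c = -1, atp_c = -1, glucan_c = 1, adp_c = 1, ppi_c = 1),
      subsystem = "Carbohydrate metabolism"),
    r("PROTS", "protein synthesis lump (average residue)",
      c(glu_c = -0.8, gln_c = -0.2, atp_c = -4.3, h2o_c = -3.3,
        protein_c = 1, adp_c = 4.3, pi_c = 4.3),
      subsystem = "Protein metabolism"),
    # pseudo-reactions
    r("NGAM", "non-growth associated ATP maintenance",
      c(atp_c = -1, h2o_c = -1, adp_c = 1, pi_c = 1),
      subsystem = "Maintenance", pseudo = TRUE),
    r("BIOMASS", "biomass pseudo-reaction",
      c(atp_c = -30, h2o_c = -30, adp_c = 30, pi_c = 30, biomass_e = 1),
      subsystem = "Biomass", pseudo = TRUE)
  )
}

#' Build the curated core metabolic model
#'
#' Constructs the bundled core network of xylose and polyol metabolism
#' (about 90 reactions across cytosol, mitochondrion and extracellular
#' space), adds the dual arabitol isoform routes and the artificial
#' arabitol pool, and installs the biomass pseudo-reaction from the given
#' composition.
#'
#' @param composition a [biomass_composition()]; default reflects the
#'   nitrogen-excess reference state.
#' @param l_route,d_route cofactor specs for [add_arabitol_pathways()].
#' @return a validated [core_model()].
#' @export
build_core_model <- function(composition = biomass_composition(),
                             l_route = c(nadph = 1, nadh = 1),
                             d_route = c(nadh = 1)) {
  model <- core_model(core_metabolite_table(), core_reaction_list(),
                      biomass_reaction_id = "BIOMASS",
                      ngam_reaction_id = "NGAM",
                      notes = "curated core model of oleaginous-yeast xylose metabolism")
  model <- add_arabitol_pathways(model, l_route = l_route, d_route = d_route)
  set_biomass_composition(model, composition)
}

#' Write the bundled core-model fixture
#'
#' Builds the curated core model with default settings, validates it, and
#' writes it to the native JSON format.
#'
#' @param path output path.
#' @return the model, invisibly.
#' @export
build_core_model_fixture <- function(path) {
  model <- build_core_model()
  rep <- validate_model(model)
  if (length(rep$imbalanced)) {
    stop("fixture model is imbalanced: ",
         paste(names(rep$imbalanced), collapse = ", "))
  }
  write_model(model, path)
  invisible(model)
}

#' Path of the bundled core-model fixture
#'
#' @return path to the JSON model shipped with the package.
#' @export
core_model_path <- function() {
  system.file("extdata", "core_model.json", package = "oleoflux",
              mustWork = TRUE)
}
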