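# Curated library of real small-molecule SMILES used by the simulator.
# Five structurally distinct super classes; CCS ground truth is synthetic
# (class power laws), the chemistry is real so descriptors and fingerprints
# are meaningful. Stereochemistry is omitted on purpose: simulated truth does
# not depend on it and canonical structures stay distinct.

.sim_structure_catalog <- function() {
  aa <- c(
    glycine = "NCC(=O)O",
    alanine = "CC(N)C(=O)O",
    serine = "OCC(N)C(=O)O",
    proline = "OC(=O)C1CCCN1",
    valine = "CC(C)C(N)C(=O)O",
    threonine = "CC(O)C(N)C(=O)O",
    cysteine = "SCC(N)C(=O)O",
    leucine = "CC(C)CC(N)C(=O)O",
    isoleucine = "CCC(C)C(N)C(=O)O",
    asparagine = "NC(=O)CC(N)C(=O)O",
    aspartate = "OC(=O)CC(N)C(=O)O",
    glutamine = "NC(=O)CCC(N)C(=O)O",
    glutamate = "OC(=O)CCC(N)C(=O)O",
    lysine = "NCCCCC(N)C(=O)O",
    methionine = "CSCCC(N)C(=O)O",
    histidine = "NC(Cc1c[nH]cn1)C(=O)O",
    phenylalanine = "NC(Cc1ccccc1)C(=O)O",
    arginine = "NC(CCCNC(=N)N)C(=O)O",
    tyrosine = "NC(Cc1ccc(O)cc1)C(=O)O",
    tryptophan = "NC(Cc1c[nH]c2ccccc12)C(=O)O")
  sugar <- c(
    glycerol = "OCC(O)CO",
    erythritol = "OCC(O)C(O)CO",
    xylitol = "OCC(O)C(O)C(O)CO",
    sorbitol = "OCC(O)C(O)C(O)C(O)CO",
    deoxyribose = "OCC1OC(O)CC1O",
    ribose = "OCC1OC(O)C(O)C1O",
    rhamnose = "CC1OC(O)C(O)C(O)C1O",
    glucose = "OCC1OC(O)C(O)C(O)C1O",
    fructose = "OCC1(O)OCC(O)C(O)C1O",
    inositol = "OC1C(O)C(O)C(O)C(O)C1O",
    glucosamine = "NC1C(O)OC(CO)C(O)C1O",
    n_acetylglucosamine = "CC(=O)NC1C(O)OC(CO)C(O)C1O",
    gluconic_acid = "OCC(O)C(O)C(O)C(O)C(=O)O",
    glucuronic_acid = "OC1OC(C(=O)O)C(O)C(O)C1O",
    sucrose = "OCC1OC(OC2(CO)OC(CO)C(O)C2O)C(O)C(O)C1O",
    maltose = "OCC1OC(OC2C(CO)OC(O)C(O)C2O)C(O)C(O)C1O",
    trehalose = "OCC1OC(OC2OC(CO)C(O)C(O)C2O)C(O)C(O)C1O",
    maltotriose = "OCC1OC(OC2C(CO)OC(OC3C(CO)OC(O)C(O)C3O)C(O)C2O)C(O)C(O)C1O")
  fa <- c(
    hexanoic_acid = "CCCCCC(=O)O",
    octanoic_acid = "CCCCCCCC(=O)O",
    decanoic_acid = "CCCCCCCCCC(=O)O",
    dodecanoic_acid = "CCCCCCCCCCCC(=O)O",
    tetradecanoic_acid = "CCCCCCCCCCCCCC(=O)O",
    pentadecanoic_acid = "CCCCCCCCCCCCCCC(=O)O",
    palmitic_acid = "CCCCCCCCCCCCCCCC(=O)O",
    palmitoleic_acid = "CCCCCCC=CCCCCCCCC(=O)O",
    heptadecanoic_acid = "CCCCCCCCCCCCCCCCC(=O)O",
    stearic_acid = "CCCCCCCCCCCCCCCCCC(=O)O",
    oleic_acid = "CCCCCCCCC=CCCCCCCCC(=O)O",
    linoleic_acid = "CCCCCC=CCC=CCCCCCCCC(=O)O",
    linolenic_acid = "CCC=CCC=CCC=CCCCCCCCC(=O)O",
    arachidic_acid = "CCCCCCCCCCCCCCCCCCCC(=O)O",
    arachidonic_acid = "CCCCCC=CCC=CCC=CCC=CCCCC(=O)O",
    eicosapentaenoic_acid = "CCC=CCC=CCC=CCC=CCC=CCCCC(=O)O",
    behenic_acid = "CCCCCCCCCCCCCCCCCCCCCC(=O)O",
    docosahexaenoic_acid = "CCC=CCC=CCC=CCC=CCC=CCC=CCCC(=O)O")
  nuc <- c(
    cytosine = "Nc1cc[nH]c(=O)n1",
    uracil = "O=c1cc[nH]c(=O)[nH]1",
    thymine = "Cc1c[nH]c(=O)[nH]c1=O",
    adenine = "Nc1ncnc2[nH]cnc12",
    hypoxanthine = "O=c1[nH]cnc2[nH]cnc12",
    guanine = "Nc1nc2[nH]cnc2c(=O)[nH]1",
    xanthine = "O=c1[nH]c(=O)c2[nH]cnc2[nH]1",
    theobromine = "Cn1cnc2c1c(=O)[nH]c(=O)n2C",
    caffeine = "Cn1cnc2c1c(=O)n(C)c(=O)n2C",
    thymidine = "Cc1cn(C2CC(O)C(CO)O2)c(=O)[nH]c1=O",
    deoxyadenosine = "Nc1ncnc2c1ncn2C1CC(O)C(CO)O1",
    cytidine = "Nc1ccn(C2OC(CO)C(O)C2O)c(=O)n1",
    uridine = "O=c1ccn(C2OC(CO)C(O)C2O)c(=O)[nH]1",
    adenosine = "Nc1ncnc2c1ncn2C1OC(CO)C(O)C1O",
    inosine = "O=c1[nH]cnc2c1ncn2C1OC(CO)C(O)C1O",
    guanosine = "Nc1nc2c(c(=O)[nH]1)ncn2C1OC(CO)C(O)C1O",
    xanthosine = "O=c1[nH]c(=O)c2ncn(C3OC(CO)C(O)C3O)c2[nH]1",
    amp = "Nc1ncnc2c1ncn2C1OC(COP(=O)(O)O)C(O)C1O")
  benz <- c(
    phenol = "Oc1ccccc1",
    catechol = "Oc1ccccc1O",
    resorcinol = "Oc1cccc(O)c1",
    hydroquinone = "Oc1ccc(O)cc1",
    benzoic_acid = "OC(=O)c1ccccc1",
    salicylic_acid = "OC(=O)c1ccccc1O",
    p_hydroxybenzoic_acid = "OC(=O)c1ccc(O)cc1",
    phenylacetic_acid = "OC(=O)Cc1ccccc1",
    mandelic_acid = "OC(C(=O)O)c1ccccc1",
    cinnamic_acid = "OC(=O)C=Cc1ccccc1",
    p_coumaric_acid = "Oc1ccc(C=CC(=O)O)cc1",
    caffeic_acid = "Oc1ccc(C=CC(=O)O)cc1O",
    ferulic_acid = "COc1cc(C=CC(=O)O)ccc1O",
    protocatechuic_acid = "OC(=O)c1ccc(O)c(O)c1",
    gallic_acid = "OC(=O)c1cc(O)c(O)c(O)c1",
    vanillic_acid = "COc1cc(C(=O)O)ccc1O",
    syringic_acid = "COc1cc(C(=O)O)cc(OC)c1O",
    hippuric_acid = "OC(=O)CNC(=O)c1ccccc1",
    tyramine = "NCCc1ccc(O)cc1",
    dopamine = "NCCc1ccc(O)c(O)c1")
  data.frame(
    id = sprintf("SIM%03d", seq_len(length(aa) + length(sugar) + length(fa) +
                                      length(nuc) + length(benz))),
    name = c(names(aa), names(sugar), names(fa), names(nuc), names(benz)),
    smiles = unname(c(aa, sugar, fa, nuc, benz)),
    superclass = rep(c("Amino acids and derivatives", "Carbohydrates",
                       "Fatty acyls", "Nucleosides and analogues",
                       "Benzenoids"),
                     c(length(aa), length(sugar), length(fa), length(nuc),
                       length(benz))),
    stringsAsFactors = FALSE)
}
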