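compound_id,charge_state,phase,energy_hartree,method_tag
ascorbic_acid,neutral,gas,-500,synthetic
ascorbic_acid,cation,gas,-499.642061598773,synthetic
ascorbic_acid,anion,gas,-500.112452926874,synthetic
citflavanone,neutral,gas,-500,synthetic
citflavanone,cation,gas,-499.733934905043,synthetic
citflavanone,anion,gas,-499.999632506775,synthetic
citflavanone,neutral,methanol,-500,synthetic
citflavanone,cation,methanol,-499.788323902355,synthetic
citflavanone,anion,methanol,-500.063943821164,synthetic
lonchocarpol_A,neutral,gas,-500,synthetic
lonchocarpol_A,cation,gas,-499.733934905043,synthetic
lonchocarpol_A,anion,gas,-499.996325067749,synthetic
lonchocarpol_A,neutral,methanol,-500,synthetic
lonchocarpol_A,cation,methanol,-499.780239051403,synthetic
lonchocarpol_A,anion,methanol,-500.060636382138,synthetic
lupinifolin,neutral,gas,-500,synthetic
lupinifolin,cation,gas,-499.737242344069,synthetic
lupinifolin,anion,gas,-500.002572452576,synthetic
lupinifolin,neutral,methanol,-500,synthetic
lupinifolin,cation,methanol,-499.78795640913,synthetic
lupinifolin,anion,methanol,-500.062841341488,synthetic
quercetin,neutral,gas,-500,synthetic
quercetin,cation,gas,-499.704902940262,synthetic
quercetin,anion,gas,-500.109880474299,synthetic
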