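"name","class","formula","monoisotopic_mass","smiles","predicted_rt"
"Abscisic acid (ABA)","abscisic acid","C15H20O4",264.136159,"CC1=CC(=O)CC(C)(C)C1(O)C=CC(C)=CC(O)=O",5.56
"7-hydroxy-ABA","abscisic acid","C15H20O5",280.131074,"OCC1=CC(=O)CC(C)(C)C1(O)C=CC(C)=CC(O)=O",5.58
"9-hydroxy-ABA","abscisic acid","C15H20O5",280.131074,"CC1=CC(=O)CC(C)(CO)C1(O)C=CC(C)=CC(O)=O",5.49
"Neophaseic acid","abscisic acid","C15H20O5",280.131074,"OCC1(C)CC(=O)C2(CC2)C1(O)C=CC(C)=CC(O)=O",6.01
"Melatonin (MEL)","melatonin conjugates","C13H16N2O2",232.121178,"CC(=O)NCCc1c[nH]c2ccc(OC)cc12",4.88
"2-hydroxymelatonin","melatonin conjugates","C13H16N2O3",248.116092,"CC(=O)NCCc1c(O)[nH]c2ccc(OC)cc12",5.07
"4-hydroxymelatonin","melatonin conjugates","C13H16N2O3",248.116092,"CC(=O)NCCc1c[nH]c2ccc(OC)c(O)c12",4.97
"6-hydroxymelatonin","melatonin conjugates","C13H16N2O3",248.116092,"CC(=O)NCCc1c[nH]c2cc(O)c(OC)cc12",5.02
"N-sinapoyl Melatonin","melatonin conjugates","C24H26N2O6",438.179087,"COc1cc(C=CC(=O)n2cc(CCNC(C)=O)c3cc(OC)ccc32)cc(OC)c1O",3.54
"Feruloyl serotonin","melatonin conjugates","C20H20N2O4",352.142307,"COc1cc(C=CC(=O)NCCc2c[nH]c3ccc(O)cc23)ccc1O",3.83
"N-Acetylserotonin","indolamines","C12H14N2O2",218.105528,"CC(=O)NCCc1c[nH]c2ccc(O)cc12",4.63
"Serotonin","indolamines","C10H12N2O",176.094963,"NCCc1c[nH]c2ccc(O)cc12",4.52
"Tryptophan","tryptophan metabolism","C11H12N2O2",204.089878,"NC(Cc1c[nH]c2ccccc12)C(O)=O",
"5-Hydroxytryptophan","tryptophan metabolism","C11H12N2O3",220.084792,"NC(Cc1c[nH]c2ccc(O)cc12)C(O)=O",3.24
"2,3-dihydroxyindole","tryptophan metabolism","C8H7NO2",149.047678,"Oc1[nH]c2ccccc2c1O",4.98
"4,6-dihydroxyquinoline","tryptophan metabolism","C9H7NO2",161.047678,"Oc1ccnc2cc(O)ccc12",
"Anthranilic acid","tryptophan metabolism","C7H7NO2",137.047678,"Nc1ccccc1C(O)=O",4.58
"6-hydroxy-kynurenate","tryptophan metabolism","C10H7NO4",205.037508,"OC(=O)c1cc(=O)c2cc(O)ccc2[nH]1",3.95
"7,8-dihydroxykynurenate","tryptophan metabolism","C10H7NO5",221.032422,"OC(=O)c1cc(=O)c2ccc(O)c(O)c2[nH]1",
"2-formylamino-benzaldehyde","tryptophan metabolism","C8H7NO2",149.047678,"O=CNc1ccccc1C=O",5.23
"5-(3'-carboxy-3'-oxopropyl)-4,6-dihydroxypicolinate","tryptophan metabolism","C10H9NO7",255.037902,"OC(=O)c1nc(O)c(CCC(=O)C(O)=O)c(O)c1",
"Glucobrassicin","tryptophan metabolism","C16H20N2O9S2",448.061022,"OCC1OC(SC(=NOS(O)(=O)=O)Cc2c[nH]c3ccccc23)C(O)C(O)C1O",
"2-methylthio-cis-zeatin","cytokinins","C11H15N5OS",265.099731,"CSc1nc(NCC=C(C)CO)c2[nH]cnc2n1",4.52
"2-methylthio-cis-zeatin riboside","cytokinins","C16H23N5O5S",397.14199,"CSc1nc(NCC=C(C)CO)c2ncn(C3OC(CO)C(O)C3O)c2n1",4.13
"Zeatin","cytokinins","C10H13N5O",219.11201,"CC(CO)=CCNc1ncnc2[nH]cnc12",3.31
"Zeatin riboside-O-glucoside","cytokinins","C21H31N5O10",513.207092,"OCC1OC(OCC(C)=CCNc2ncnc3c2ncn3C2OC(CO)C(O)C2O)C(O)C(O)C1O",4.05
"Isopentenyl adenine","cytokinins","C10H13N5",203.117095,"CC(C)=CCNc1ncnc2[nH]cnc12",3.93
"Kinetin","cytokinins","C10H9N5O",215.08071,"C(Nc1ncnc2[nH]cnc12)c1ccco1",5.32
"6-Benzylaminopurine","cytokinins","C12H11N5",225.101445,"C(Nc1ncnc2[nH]cnc12)c1ccccc1",4.53
"Indole-3-acetic acid","auxins","C10H9NO2",175.063329,"OC(=O)Cc1c[nH]c2ccccc12",4.2
"Indole-3-butyric acid","auxins","C12H13NO2",203.094629,"OC(=O)CCCc1c[nH]c2ccccc12",6.05
"1-Naphthaleneacetic acid","auxins","C12H10O2",186.06808,"OC(=O)Cc1cccc2ccccc12",6.48
"IAA aspartate","auxins","C14H14N2O5",290.090272,"OC(=O)CC(NC(=O)Cc1c[nH]c2ccccc12)C(O)=O",
"IAA glutamate","auxins","C15H16N2O5",304.105922,"OC(=O)CCC(NC(=O)Cc1c[nH]c2ccccc12)C(O)=O",
"Jasmonic acid","jasmonates","C12H18O3",210.125594,"CCC=CCC1C(CC(O)=O)CCC1=O",5.97
"Gibberellin A3","gibberellins","C19H22O6",346.141638,"CC12C(O)C=CC3(OC1=O)C1CCC4(O)CC1(CC4=C)C(C(O)=O)C23",5.63
"Coumaric acid","salicylates","C9H8O3",164.047344,"OC(=O)C=Cc1ccc(O)cc1",4.59
"Ferulic acid","salicylates","C10H10O4",194.057909,"COc1cc(C=CC(O)=O)ccc1O",4.89
"Histidine","catecholamines","C6H9N3O2",155.069477,"NC(Cc1cnc[nH]1)C(O)=O",2.45
"Norepinephrine","catecholamines","C8H11NO3",169.073893,"NCC(O)c1ccc(O)c(O)c1",3.57
"Quercetin","salicylates","C15H10O7",302.042653,"Oc1cc(O)c2c(=O)c(O)c(-c3ccc(O)c(O)c3)oc2c1",4.92
"Brassinolide","steroids","C28H48O6",480.345089,"CC(C)C(C)C(O)C(O)C(C)C1CCC2C1(C)CCC1C2CC(=O)OC2CC(O)C(O)CC12C",5.91
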