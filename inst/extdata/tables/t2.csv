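compound_id,name,smiles,chemical_class,pharmacophore_hit,active_orthosteric,isomer_mixture
II,Isopropyl cinnamate,CC(C)OC(=O)/C=C/c1ccccc1,cinnamate ester,TRUE,TRUE,FALSE
IV,Ethyl cinnamate,CCOC(=O)/C=C/c1ccccc1,cinnamate ester,TRUE,TRUE,FALSE
4,Linalyl acetate,CC(C)=CCCC(C)(C=C)OC(C)=O,monoterpene ester,TRUE,TRUE,FALSE
39,"2,4-Octadienal",CCC/C=C/C=C/C=O,fatty aldehyde,TRUE,TRUE,FALSE
33,2-Heptanone,CCCCCC(C)=O,ketone,TRUE,FALSE,FALSE
40,6-Methyl-5-hepten-2-one,CC(=O)CCC=C(C)C,ketone,TRUE,FALSE,FALSE
42,4-Octanone,CCCC(=O)CCCC,ketone,TRUE,FALSE,FALSE
43,2-Octanone,CCCCCCC(C)=O,ketone,TRUE,FALSE,FALSE
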