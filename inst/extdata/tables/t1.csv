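compound_id,name,smiles,chemical_class,antagonist_type,isomer_mixture
I,Carvacrol,Cc1ccc(C(C)C)cc1O,monoterpene alcohol,allosteric,FALSE
II,Isopropyl cinnamate,CC(C)OC(=O)/C=C/c1ccccc1,cinnamate ester,orthosteric,FALSE
III,Cumin alcohol,CC(C)c1ccc(CO)cc1,monoterpene alcohol,allosteric,FALSE
IV,Ethyl cinnamate,CCOC(=O)/C=C/c1ccccc1,cinnamate ester,orthosteric,FALSE
4,Linalyl acetate,CC(C)=CCCC(C)(C=C)OC(C)=O,monoterpene ester,orthosteric,FALSE
39,"2,4-Octadienal",CCC/C=C/C=C/C=O,fatty aldehyde,orthosteric,FALSE
45,(1S)-3-Carene,CC1=CC[C@H]2[C@@H](C1)C2(C)C,monoterpene,allosteric,FALSE
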