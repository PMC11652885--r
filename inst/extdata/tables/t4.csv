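compound_id,name,smiles,chemical_class,pharmacophore_hit,ic50_uM,isomer_mixture
62,alpha-Pinene oxide,CC1(C)C2CC1C1(C)OC1C2,monoterpene epoxide,FALSE,52,FALSE
64,Borneol,CC1(C)C2CCC1(C)C(O)C2,monoterpene alcohol,FALSE,86.5,FALSE
66,2-Methylquinoline,Cc1ccc2ccccc2n1,quinoline,FALSE,115,FALSE
75,Aromadendrene,CC1CCC2C1C1C(C1(C)C)CCC2=C,sesquiterpene,FALSE,26.2,FALSE
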