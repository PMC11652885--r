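compound_id,name,smiles,chemical_class,retained,response_pct,isomer_mixture
5284507,Nerolidol,CC(C)=CCC/C(C)=C/CC[C@](C)(O)C=C,sesquiterpene alcohol,TRUE,51,FALSE
31289,Nonanal,CCCCCCCCC=O,fatty aldehyde,TRUE,65,FALSE
637566,Geraniol,CC(C)=CCC/C(C)=C/CO,acyclic monoterpene alcohol,TRUE,43,FALSE
638011,Citral,CC(C)=CCC/C(C)=C/C=O,monoterpene aldehyde,TRUE,69,FALSE
8294,Linalyl acetate,CC(C)=CCCC(C)(C=C)OC(C)=O,monoterpene ester,TRUE,59,FALSE
7439,Carvone,CC1=CC[C@@H](CC1=O)C(C)=C,monoterpene ketone,FALSE,71,FALSE
1549026,Geranyl acetate,CC(C)=CCC/C(C)=C/COC(C)=O,monoterpene ester,FALSE,67,FALSE
1549778,Geranyl acetone,CC(C)=CCC/C(C)=C/CCC(C)=O,monoterpene ketone,FALSE,92,FALSE
379,Octanoic Acid,CCCCCCCC(=O)O,fatty acid,FALSE,81,FALSE
6549,Linalool,CC(C)=CCCC(C)(O)C=C,monoterpene alcohol,FALSE,98,FALSE
17100,alpha-Terpineol,CC1=CCC(CC1)C(C)(C)O,monoterpene alcohol,FALSE,100,FALSE
31253,Myrcene,CC(C)=CCCC(=C)C=C,monoterpene,FALSE,71,FALSE
8892,Hexanoic Acid,CCCCCC(=O)O,fatty acid,FALSE,59,FALSE
14525,Fenchone,CC1(C)C2CCC(C)(C2)C1=O,monoterpene ketone,FALSE,67,FALSE
22311,Limonene,CC1=CCC(CC1)C(C)=C,monoterpene,FALSE,82,FALSE
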