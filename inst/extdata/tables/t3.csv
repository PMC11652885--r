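compound_id,name,smiles,chemical_class,pharmacophore_hit,ic50_uM,active_orthosteric,isomer_mixture
53,2-Nonanone,CCCCCCCC(C)=O,ketone,TRUE,NA,FALSE,FALSE
54,(Z)-3-Nonen-1-ol,CCCCC/C=C\CCO,aliphatic alcohol,TRUE,48.9,TRUE,FALSE
57,Pulegone,CC1CCC(=C(C)C)C(=O)C1,monoterpene ketone,TRUE,NA,FALSE,FALSE
59,Limonene oxide (cis/trans mix),CC12OC1CCC(C2)C(C)=C,monoterpene epoxide,TRUE,NA,FALSE,TRUE
60,"(2E,4E)-Decadienal",CCCCC/C=C/C=C/C=O,fatty aldehyde,TRUE,66.7,TRUE,FALSE
65,p-Menth-1-en-9-ol,CC1=CCC(CC1)C(C)CO,monoterpene alcohol,TRUE,NA,FALSE,FALSE
68,cis-Jasmone,CC/C=C\CC1=C(C)CCC1=O,terpenoid,TRUE,NA,FALSE,FALSE
71,gamma-Undecalactone,CCCCCCCC1CCC(=O)O1,lactone,TRUE,NA,FALSE,FALSE
72,2-Tridecanone,CCCCCCCCCCCC(C)=O,ketone,TRUE,NA,FALSE,FALSE
74,Bisabolene (mix of isomers),CC1=CCC(CC1)C(C)=CCC=C(C)C,sesquiterpene,FALSE,47.7,TRUE,TRUE
77,alpha-Bisabolol,CC1=CCC(CC1)C(C)(O)CCC=C(C)C,sesquiterpene alcohol,TRUE,47,TRUE,FALSE
78,1-Hexadecanol,CCCCCCCCCCCCCCCCO,fatty alcohol,TRUE,NA,FALSE,FALSE
79,Phytol,CC(C)CCCC(C)CCCC(C)CCC/C(C)=C/CO,terpenoid,TRUE,NA,FALSE,FALSE
81,(Z)-Octadec-11-ene nitrile,N#CCCCCCCCCC/C=C\CCCCCC,fatty nitrile,TRUE,NA,FALSE,FALSE
83,13-Methyl tetradec-3-ene nitrile,N#CC/C=C/CCCCCCCCC(C)C,fatty nitrile,TRUE,25,TRUE,FALSE
84,"(9Z,12Z,15S)-Octadeca-9,12-dien-15-olide",O=C1CCCCCCC/C=C\C/C=C\C[C@@H](CCC)O1,macrocyclic unsaturated lactone,TRUE,NA,FALSE,FALSE
85,N-(3-Methyl butyryl)-O-(2-methyl propionyl)-L-serine methyl ester,COC(=O)[C@H](COC(=O)C(C)C)NC(=O)CC(C)C,diester amide,TRUE,NA,FALSE,FALSE
88,Ethyl (E/Z)-2-(cyclohex-2-en-1-ylidene) acetate (mix of isomers),CCOC(=O)/C=C1\CCCC=C1,ester,TRUE,195.7,TRUE,TRUE
89,7-Tetradecynoic acid,CCCCCCC#CCCCCCC(=O)O,unsaturated fatty acid,TRUE,NA,FALSE,FALSE
93,N-Phenylethyl-2-methyl propionic acid amide,CC(C)C(=O)NCCc1ccccc1,peptide,TRUE,NA,FALSE,FALSE
94,(R)-2-Heptyl acetate,CCCCC[C@@H](C)OC(C)=O,ester,TRUE,NA,FALSE,FALSE
95,2-Pentyl 2-methylbutanoate,CCC(C)C(=O)OC(C)CCC,ester,TRUE,NA,FALSE,FALSE
96,13-Methyl tetradecane-1-ol,CC(C)CCCCCCCCCCCCO,fatty alcohol,TRUE,NA,FALSE,FALSE
98,(E)-3-Methyl-2-(3-methylbutyliden)-4-butanolide,O=C1OC[C@@H](C)/C1=C/CC(C)C,lactone,TRUE,43.2,TRUE,FALSE
99,"(4R,6R,8R)-Trimethyldecan-2-one",CC[C@H](C)C[C@H](C)C[C@H](C)CC(C)=O,ketone,TRUE,57,TRUE,FALSE
u01,appendix VOC 01 (synthetic placeholder; not printed in main text),NA,unknown,FALSE,NA,FALSE,FALSE
u02,appendix VOC 02 (synthetic placeholder; not printed in main text),NA,unknown,FALSE,NA,FALSE,FALSE
u03,appendix VOC 03 (synthetic placeholder; not printed in main text),NA,unknown,FALSE,NA,FALSE,FALSE
u04,appendix VOC 04 (synthetic placeholder; not printed in main text),NA,unknown,FALSE,NA,FALSE,FALSE
u05,appendix VOC 05 (synthetic placeholder; not printed in main text),NA,unknown,FALSE,NA,FALSE,FALSE
u06,appendix VOC 06 (synthetic placeholder; not printed in main text),NA,unknown,FALSE,NA,FALSE,FALSE
u07,appendix VOC 07 (synthetic placeholder; not printed in main text),NA,unknown,FALSE,NA,FALSE,FALSE
u08,appendix VOC 08 (synthetic placeholder; not printed in main text),NA,unknown,FALSE,NA,FALSE,FALSE
u09,appendix VOC 09 (synthetic placeholder; not printed in main text),NA,unknown,FALSE,NA,FALSE,FALSE
u10,appendix VOC 10 (synthetic placeholder; not printed in main text),NA,unknown,FALSE,NA,FALSE,FALSE
u11,appendix VOC 11 (synthetic placeholder; not printed in main text),NA,unknown,FALSE,NA,FALSE,FALSE
u12,appendix VOC 12 (synthetic placeholder; not printed in main text),NA,unknown,FALSE,NA,FALSE,FALSE
u13,appendix VOC 13 (synthetic placeholder; not printed in main text),NA,unknown,FALSE,NA,FALSE,FALSE
u14,appendix VOC 14 (synthetic placeholder; not printed in main text),NA,unknown,FALSE,NA,FALSE,FALSE
u15,appendix VOC 15 (synthetic placeholder; not printed in main text),NA,unknown,FALSE,NA,FALSE,FALSE
u16,appendix VOC 16 (synthetic placeholder; not printed in main text),NA,unknown,FALSE,NA,FALSE,FALSE
u17,appendix VOC 17 (synthetic placeholder; not printed in main text),NA,unknown,FALSE,NA,FALSE,FALSE
u18,appendix VOC 18 (synthetic placeholder; not printed in main text),NA,unknown,FALSE,NA,FALSE,FALSE
u19,appendix VOC 19 (synthetic placeholder; not printed in main text),NA,unknown,FALSE,NA,FALSE,FALSE
u20,appendix VOC 20 (synthetic placeholder; not printed in main text),NA,unknown,FALSE,NA,FALSE,FALSE
u21,appendix VOC 21 (synthetic placeholder; not printed in main text),NA,unknown,FALSE,NA,FALSE,FALSE
u22,appendix VOC 22 (synthetic placeholder; not printed in main text),NA,unknown,FALSE,NA,FALSE,FALSE
u23,appendix VOC 23 (synthetic placeholder; not printed in main text),NA,unknown,FALSE,NA,FALSE,FALSE
u24,appendix VOC 24 (synthetic placeholder; not printed in main text),NA,unknown,FALSE,NA,FALSE,FALSE
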