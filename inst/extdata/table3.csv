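cluster,reference_id,subset,member,smiles
SOM16-Cl-2,V,V-s,Vanillyl isobutyrate,COc1cc(COC(=O)C(C)C)ccc1O
SOM16-Cl-2,V,V-s,Vanillin propylene glycol acetal,COc1cc(C2OCC(C)O2)ccc1O
SOM16-Cl-2,V,V-s,Ethyl vanillin isobutyrate,CCOc1cc(C=O)ccc1OC(=O)C(C)C
SOM16-Cl-2,V,V-s,1-Ethoxy-2-methoxybenzene,CCOc1ccccc1OC
SOM16-Cl-2,V,V-s,Dimethyl hydroquinone,COc1ccc(OC)cc1
SOM16-Cl-2,V,V-s,Ethyl vanillin,CCOc1cc(C=O)ccc1O
SOM16-Cl-2,V,V-s,Vanillyl acetate,COc1cc(COC(C)=O)ccc1O
SOM16-Cl-2,V,V-s,Vanillylidene acetone,COc1cc(/C=C/C(C)=O)ccc1O
SOM16-Cl-2,V,V-s,Vanillin hexylene glycol acetal,COc1cc(C2OC(C)CC(C)(C)O2)ccc1O
SOM16-Cl-2,V,V-s,Ethyl vanillin hexylene glycol acetal,CCOc1cc(C2OC(C)CC(C)(C)O2)ccc1O
SOM16-Cl-2,V,V-s,Ethyl vanillin propylene glycol acetal,CCOc1cc(C2OCC(C)O2)ccc1O
SOM16-Cl-4,WL,WL-s,7-Methyltetrahydronaphthalenone,Cc1ccc2CCCC(=O)c2c1
SOM16-Cl-4,WL,WL-s,delta-Heptalactone,CCC1CCCC(=O)O1
SOM16-Cl-4,WL,WL-s,Menthofurolactone,NA
SOM16-Cl-4,WL,WL-s,Octahydrocoumarin,O=C1CCC2CCCCC2O1
SOM16-Cl-4,WL,WL-s,Laitone,NA
SOM16-Cl-4,WL,WL-s,Coconut naphthalenone,NA
SOM16-Cl-4,WL,WL-s,(R)-Tonka furanone,NA
SOM16-Cl-4,WL,WL-s,Dihydromint lactone,CC1CCC2C(C1)OC(=O)C2C
SOM16-Cl-5,F,F-s,Anisyl isobutyrate,COc1ccc(COC(=O)C(C)C)cc1
SOM16-Cl-5,F,F-s,4-Hydroxyphenethyl alcohol,OCCc1ccc(O)cc1
SOM16-Cl-5,F,F-s,4-(para-Tolyl)-2-butanone,CC(=O)CCc1ccc(C)cc1
SOM16-Cl-5,F,F-s,Tufurol acetate,NA
SOM16-Cl-5,F,F-s,2-Methylbenzyl acetate,CC(=O)OCc1ccccc1C
SOM16-Cl-5,F,F-s,alpha-Methylbenzyl propionate,CCC(=O)OC(C)c1ccccc1
SOM16-Cl-5,F,F-s,Phenethyl 2-methylbutyrate,CCC(C)C(=O)OCCc1ccccc1
SOM16-Cl-5,F,F-s,Methyl 4-phenylbutyrate,COC(=O)CCCc1ccccc1
SOM16-Cl-5,F,F-s,Benzyl acetoacetate,CC(=O)CC(=O)OCc1ccccc1
SOM16-Cl-8,bI,bI-s,beta-Ionyl acetate,CC(OC(C)=O)/C=C/C1=C(C)CCCC1(C)C
SOM16-Cl-8,bI,bI-s,alpha-Ionol,CC(O)/C=C/C1C(C)=CCCC1(C)C
SOM16-Cl-8,bI,bI-s,alpha-Ionyl acetate,CC(OC(C)=O)/C=C/C1C(C)=CCCC1(C)C
SOM16-Cl-8,bI,bI-s,3-Methylcyclohexyl acetate,CC1CCCC(C1)OC(C)=O
SOM16-Cl-8,bI,bI-s,beta-Irone,CC(=O)/C=C/C1=C(C)CC(C)CC1(C)C
SOM16-Cl-8,bI,bI-s,Campholene acetate,CC1=CCC(CCOC(C)=O)C1(C)C
SOM16-Cl-8,bI,bI-s,Nopyl acetate,CC(=O)OCCC1=CCC2CC1C2(C)C
SOM16-Cl-8,bI,bI-s,4-Dimethyl ionone,NA
SOM16-Cl-8,bD,bD-s,Plum damascone (high alpha),NA
SOM16-Cl-8,bD,bD-s,(Z)-alpha-Damascone,C/C=C\C(=O)C1C(C)=CCCC1(C)C
SOM16-Cl-8,bD,bD-s,Cyclohexylethyl isovalerate,CC(C)CC(=O)OCCC1CCCCC1
SOM16-Cl-8,bD,bD-s,Cyclohexylethyl valerate,CCCCC(=O)OCCC1CCCCC1
SOM16-Cl-8,bD,bD-s,1-(3-(Methylthio)butyryl)-2-6-6-trimethylcyclohexene,CSC(C)CC(=O)C1=C(C)CCCC1(C)C
SOM16-Cl-8,bD,bD-s,Methyl 2-6-6-trimethyl-3-cyclohexene-1-carboxylate,COC(=O)C1C(C)C=CCC1(C)C
SOM16-Cl-13,IA,IA-s,2-Methylbutyl butyrate,CCCC(=O)OCC(C)CC
SOM16-Cl-13,IA,IA-s,Hexyl acetate,CCCCCCOC(C)=O
SOM16-Cl-13,IA,IA-s,Isobutyl propionate,CCC(=O)OCC(C)C
SOM16-Cl-13,IA,IA-s,Methyl butyrate,CCCC(=O)OC
SOM16-Cl-13,IA,IA-s,Isopropyl propionate,CCC(=O)OC(C)C
SOM16-Cl-13,IA,IA-s,Methyl 4-methylvalerate,COC(=O)CCC(C)C
SOM16-Cl-13,IA,IA-s,Isoamyl butyrate,CCCC(=O)OCCC(C)C
SOM16-Cl-13,IA,IA-s,Propyl acetate,CCCOC(C)=O
SOM16-Cl-13,IA,IA-s,Butyl acetate,CCCCOC(C)=O
SOM16-Cl-13,IA,IA-s,Amyl acetate,CCCCCOC(C)=O
SOM16-Cl-14,EA,EA-s,2-Methylbut-2-enyl formate,CC=C(C)COC=O
SOM16-Cl-14,EA,EA-s,Isobutyl pyruvate,CC(=O)C(=O)OCC(C)C
SOM16-Cl-14,EA,EA-s,Methyl acetate,COC(C)=O
SOM16-Cl-14,EA,EA-s,Methyl (E)-2-butenoate,C/C=C/C(=O)OC
SOM16-Cl-14,EA,EA-s,Ethyl 2-methylbutyrate,CCC(C)C(=O)OCC
SOM16-Cl-14,EA,EA-s,2-Methylbutyl propionate,CCC(=O)OCC(C)CC
SOM16-Cl-14,EA,EA-s,Isopropyl acetate,CC(C)OC(C)=O
SOM16-Cl-14,EA,EA-s,Ethyl nitrite,CCON=O
SOM16-Cl-14,EA,EA-s,Hexyl lactate,CCCCCCOC(=O)C(C)O
SOM16-Cl-14,EA,EA-s,Methyl 3-hydroxybutyrate,COC(=O)CC(C)O
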