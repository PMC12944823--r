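pdb	protein	smiles
5mli	bromodomain	CNc1cnn(c(=O)c1Cl)C
4o7a	bromodomain	Clc1cccc(c1)C1=C(Nc2ccc(c(c2)Cl)O)C(=O)NC1=O
4hbw	bromodomain	CCNS(=O)(=O)c1ccc2c(c1)CN(C(=O)N2)C
5igk	bromodomain	CCOC(=O)Nc1cc(nn2c1nnc2C)c1ccc(c(c1)NS(=O)(=O)C)C
5khm	bromodomain	COc1nnc2n1nc(cc2)N1CCC(CC1)c1ccc(cc1)OCC[N@H+]1CCN(C(=O)[C@H]1C)C
3iw8	p38_kinase	O=C(Nc1scc(n1)[C@@H](COCc1ccccc1)[NH3+])Nc1ccc(c(c1)Cl)F
3iw7	p38_kinase	SCc1ccc(cc1)C(=O)N1CCC(CC1)Cc1ccccc1
6m95	p38_kinase	COc1cc(SC)ccc1C(=O)N1CCC(CC1)Cc1ccccc1
3l8s	p38_kinase	O=C(Nc1snc(c1C(=O)N)OCc1c(F)cc(cc1F)Br)NCCCC[NH+]1CCCC1
6ohd	p38_kinase	Cc1ccc(cc1c1cnc2c(c1)[nH]c(=O)n2C(C)(C)C)C(=O)Nc1nocc1
4xh6	pim1_kinase	COc1c(O)cc2c(c1O)c(=O)cc(o2)c1ccc(cc1)O
5kcx	pim1_kinase	C[NH+]1CCN(CC1)c1ccc(cc1)c1cc2c(n1C)nc(cc2Cl)C(=O)N
4xhk	pim1_kinase	O=C(c1csc(n1)c1c(F)cccc1F)Nc1cnccc1O[C@@H]1C[NH2+]CC1
5v82	pim1_kinase	Cc1cncc(n1)c1ncc2c(c1)n(nc2)c1cccc(n1)[C@H]1C[NH2+]CCC1(F)F
4n70	pim1_kinase	C[C@H]1CN(C[C@H]([C@@H]1O)[NH3+])c1cc[nH+]cc1NC(=O)c1ccc(c(n1)c1c(F)cccc1F)F
3zpr	beta1_receptor	Cc1cc(nc2c1cccc2)N1CC[NH2+]CC1
3zpq	beta1_receptor	C1[NH2+]CCN(C1)c1cccc2c1cc[nH]2
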