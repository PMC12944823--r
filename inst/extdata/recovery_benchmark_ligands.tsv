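pdb	target_smiles	reported_result_smiles	reported_dice
4lzs	CNC(=O)c1[nH]c(c(c1CC)C(=O)C)C	CCc1c(C(=O)NC)[nH]c(C)c1C(C)=O	1.00
5mli	CNc1cnn(c(=O)c1Cl)C	CNc1cnn(C)c(=O)c1Cl	1.00
3vc4	O=C1NC(=O)/C(=C/c2cccc(c2)C(F)(F)F)/S1	O=C1NC(=O)C(=Cc2cccc(C(F)(F)F)c2)S1	1.00
6fnx	CCn1cnc2c1c(=O)[nH]c(=O)n2Cc1ccccc1	CCn1cnc2c1c(P)nc(=O)n2Cc1ccccc1	0.905
2yek	CCNC(=O)C[C@@H]1N=C(c2ccc(cc2)Cl)c2c(-n3c1nnc3C)ccc(c2)OC	CCN=NC1=C2C=CC=C2C(OC)=CC1c1nc(C=CCl)c(C)n1C1=CCC(=O)NC1	0.726
4a9i	CC(=O)c1cc(c2n1cccc2)c1ccccn1	CC(=O)c1cc(-c2ccccn2)c2ccccn12	1.00
3iw7	SCc1ccc(cc1)C(=O)N1CCC(CC1)Cc1ccccc1	O=C(c1ccc(CS)cc1)N1CCC(Cc2ccccc2)CC1	1.00
1di9	COc1cc2c(ncnc2cc1OC)Nc1cccc(c1)SC	COc1cc2ncnc(Nc3cccc([SH]C)c3)c2cc1OC	1.00
1mnc	CNC(=O)[C@H](Cc1ccccc1)NC(=O)[C@@H](CC(=O)NO)CC(C)C	CNC(=O)C(Cc1ccccc1)NC(=O)C(CC(=O)NO)CC(C)C	1.00
1a07	CCCCCN(C(=O)[C@@H](NC(=O)[C@H](Cc1ccccc1)NC(=O)C)CCC(=O)[O-])CCCCC	CC=CC=CC1=CC(=O)NC(C(=O)NC(CCC(=O)O)C(=O)N(CCCCC)CCCCC)C1	0.907
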