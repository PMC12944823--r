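attempt	smiles	composite	confidence	sa_raw	esol_raw	qed
1	CCOC1(C)COc2cc(NC)n(OC)c(=S)c2N(C)C1	0.908	0.902	4.347	-2.954	0.857
2	C=CNCC1Cn2cc(C)c(C)c2C2=C1c1c(nnc(C)c1CC)C2	0.919	0.917	4.405	-4.240	0.929
3	CCC1CCC(C)(N)N1CCCn1oc(=NC)n(C)c1=O	0.918	0.908	4.798	-1.687	0.844
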