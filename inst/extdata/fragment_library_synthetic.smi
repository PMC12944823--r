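# Synthetic 50-fragment BRICS library derived from the packaged
# reference ligand SMILES (a stand-in for a random database draw).
C(=O)(N)[6*]
C1(=NC(=CC=C1)[14*])[14*]
C(=O)(C(C[8*])[4*])[1*]
C1(=NC=CC=C1)[14*]
C1(=C2C(=CC=C1)NC=C2)[16*]
C1(=C(C=CC(=C1)[16*])[16*])[16*]
S(C)[11*]
O=C1SC(C(N1)=O)=[7*]
C(=O)([1*])[1*]
CC1=C2C(=NC(=C1)[14*])C=CC=C2
C=1(C=2N(N=C(C=1)[14*])C(=NN=2)C)[16*]
C1(=CC(=C(C=C1)F)Cl)[16*]
C1(=CC=C(C=C1)[16*])[16*]
C(=O)(C(CC(=O)NO)CC(C)C)[1*]
C1(=C(C=C(C=C1F)Br)F)[16*]
C1(CNCCC1(F)F)[15*]
C1(=C(C(=C(N1)C)[16*])[16*])[14*]
C(C[4*])[4*]
C1(CNCC1)[15*]
CCCCC[4*]
CC1=NC(=CN=C1)[14*]
C1(=C(C=CN=C1)[16*])[16*]
ClC1=CC(=CC=C1)[16*]
C([8*])[4*]
C(=O)(C)[6*]
C=1(N(C=2C(C=1)=C(C=C(N=2)[14*])Cl)C)[14*]
S(=O)(=O)(C1=CC2=C(C=C1)NC(N(C2)C)=O)[12*]
N([5*])([5*])[5*]
C=1(N2C(=NN=1)C=CC(=N2)[14*])[14*]
C=1(C=CON=1)[14*]
C1(=CC(=C(C=C1)O)Cl)[16*]
N1(CCNCC1)[5*]
C(=O)(C)[1*]
C(=O)(CC3N=C(C1=CC=C(C=C1)Cl)C2=CC(=CC=C2N4C(=NN=C34)C)[16*])[1*]
C1(=C(C=C2C(=C1)C(=NC=N2)[14*])[16*])[16*]
C(C1=CC(=CC=C1)[16*])=[7*]
C(C)[8*]
C1(=CC=C(C=C1)O)[16*]
C1(=NC(=C(C=C1)F)[14*])[14*]
CC[4*]
C(C[4*])(N)[8*]
C1(=C(C2=C(C=C1O)OC(=CC2=O)[14*])O)[16*]
O([3*])[3*]
C(=O)([6*])[1*]
C1(=NC(=CS1)[14*])[14*]
C(C)(C)(C)[8*]
N1(CCN(C(=O)C1C)C)[5*]
N1(CCCC1)[5*]
C1(=CC(=CC=C1)[16*])[16*]
C=1(N2C(=C(C=1)[16*])C=CC=C2)[14*]
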