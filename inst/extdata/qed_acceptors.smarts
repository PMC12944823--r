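# Hydrogen-bond-acceptor SMARTS patterns of the QED descriptor set.
[oH0;X2]
[OH1;X2;v2]
[OH0;X2;v2]
[OH0;X1;v2]
[O-;X1]
[SH0;X2;v2]
[SH0;X1;v2]
[S-;X1]
[nH0;X2]
[NH0;X1;v3]
[$([N;+0;X3;v3]);!$(N[C,S]=O)]
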