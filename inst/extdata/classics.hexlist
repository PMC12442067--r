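> benzene
0 0 0

> naphthalene
0 0 0
1 0 0

> anthracene
0 0 0
1 0 0
2 0 0

> phenanthrene
0 0 0
1 0 0
1 1 0

> triphenylene
0 0 0
1 0 0
-1 1 0
0 -1 0

> benzo[c]phenanthrene
0 0 0
1 0 0
1 1 0
0 2 0

> pyrene
0 0 0
1 0 0
0 1 0
1 -1 0

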