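pot,treatment,focal,neighbour,density,seeds
1,dry,i,none,0,95
2,dry,i,none,0,108
3,dry,i,conspecific,4,43
4,dry,i,conspecific,4,48
5,dry,i,heterospecific,4,52
6,dry,i,heterospecific,4,60
7,dry,i,conspecific,20,13
8,dry,i,conspecific,20,16
9,dry,i,heterospecific,20,18
10,dry,i,heterospecific,20,22
11,dry,j,none,0,140
12,dry,j,none,0,159
13,dry,j,conspecific,4,55
14,dry,j,conspecific,4,61
15,dry,j,heterospecific,4,70
16,dry,j,heterospecific,4,81
17,dry,j,conspecific,20,15
18,dry,j,conspecific,20,19
19,dry,j,heterospecific,20,23
20,dry,j,heterospecific,20,27
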