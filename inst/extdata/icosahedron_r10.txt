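neovb-mesh 1
12 20
-5.2573111211913357 8.5065080835203997 0
5.2573111211913357 8.5065080835203997 0
-5.2573111211913357 -8.5065080835203997 0
5.2573111211913357 -8.5065080835203997 0
0 -5.2573111211913357 8.5065080835203997
0 5.2573111211913357 8.5065080835203997
0 -5.2573111211913357 -8.5065080835203997
0 5.2573111211913357 -8.5065080835203997
8.5065080835203997 0 -5.2573111211913357
8.5065080835203997 0 5.2573111211913357
-8.5065080835203997 0 -5.2573111211913357
-8.5065080835203997 0 5.2573111211913357
0 11 5
0 5 1
0 1 7
0 7 10
0 10 11
1 5 9
5 11 4
11 10 2
10 7 6
7 1 8
3 9 4
3 4 2
3 2 6
3 6 8
3 8 9
4 9 5
2 4 11
6 2 10
8 6 7
9 8 1
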