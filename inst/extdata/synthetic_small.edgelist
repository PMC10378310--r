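# synthetic 12-node test network (not derived from any real dataset)
0 1
0 2
0 3
1 2
1 4
2 5
3 6
4 5
4 7
5 8
6 7
6 9
7 10
8 11
9 10
10 11
3 8
2 9
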