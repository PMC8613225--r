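*Vertices 6
1 "hub"
2 "l1"
3 "l2"
4 "mid"
5 "tail1"
6 "tail2"
*Edges
1 2
1 3
1 4
4 5
*Arcs
5 6
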