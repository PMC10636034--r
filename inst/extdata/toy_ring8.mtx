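%%MatrixMarket matrix coordinate pattern symmetric
8 8 8
2 1
3 2
4 3
5 4
6 5
7 6
8 7
8 1
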