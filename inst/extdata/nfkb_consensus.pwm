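>nfkb_consensus
A C G T
0.001 0.001 0.997 0.001
0.001 0.001 0.997 0.001
0.001 0.001 0.997 0.001
0.997 0.001 0.001 0.001
0.997 0.001 0.001 0.001
0.001 0.001 0.001 0.997
0.001 0.001 0.001 0.997
0.001 0.001 0.001 0.997
0.001 0.997 0.001 0.001
0.001 0.997 0.001 0.001
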