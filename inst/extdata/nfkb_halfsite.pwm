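>nfkb_halfsite
A C G T
0.02 0.02 0.94 0.02
0.02 0.02 0.94 0.02
0.02 0.02 0.94 0.02
0.47 0.03 0.47 0.03
0.25 0.25 0.25 0.25
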