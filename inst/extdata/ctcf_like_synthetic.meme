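MEME version 4

ALPHABET= ACGT

Background letter frequencies
A 0.250000 C 0.250000 G 0.250000 T 0.250000

MOTIF CTCF_like_synthetic
letter-probability matrix: alength= 4 w= 12
0.006000 0.970000 0.006000 0.018000
0.028000 0.860000 0.084000 0.028000
0.720000 0.056000 0.168000 0.056000
0.018000 0.910000 0.018000 0.054000
0.114000 0.810000 0.038000 0.038000
0.660000 0.068000 0.204000 0.068000
0.036000 0.012000 0.940000 0.012000
0.072000 0.024000 0.880000 0.024000
0.048000 0.144000 0.048000 0.760000
0.048000 0.016000 0.920000 0.016000
0.032000 0.032000 0.840000 0.096000
0.228000 0.620000 0.076000 0.076000
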