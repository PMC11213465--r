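# synthetic example count matrix, NFAT-like site (columns: A C G T)
20 0 0 0
0 0 0 20
0 0 20 0
0 0 20 0
20 0 0 0
20 0 0 0
20 0 0 0
20 0 0 0
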