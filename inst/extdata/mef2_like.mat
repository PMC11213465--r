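# synthetic example count matrix, MEF2-like A/T-rich box (columns: A C G T)
0 20 0 0
0 0 0 20
20 0 0 0
20 0 0 0
20 0 0 0
20 0 0 0
20 0 0 0
0 0 0 20
20 0 0 0
0 0 20 0
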