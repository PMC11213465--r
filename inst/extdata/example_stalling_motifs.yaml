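# Synthetic EXAMPLE stalling-motif catalogue for tests and demos only;
# not a curated canonical set.  Categories map to lists of fixed
# amino-acid motifs (single-letter code).
polyproline: [PPP, PPG]
proline_glycine: [GPG, PGP]
polybasic: [KKK, KKR, KRK, RKK, RRR]
polyacidic: [DDD, EEE, DED, EDE]
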