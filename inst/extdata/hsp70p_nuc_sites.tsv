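hsp70p_nuc	55	67	site1	+	acceptor=Cy7
hsp70p_nuc	97	104	site2	+	acceptor=Cy5
hsp70p_nuc	113	114	dyad	+	dyad
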