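>hsp70p_nuc
GAGACGTAGGTCCCTCGCCGTACCCACTGGCTAGTTCGCCAAAACATTATAGTAAGAGAGAGAGAGACTGCACAAATCTT
ACCGGCGACGCGGGGAAGAGAGAGATATCCCCCATGACTCACGAGGAGCTGTCGAAGGCTATTCGGGATACTCAACCTTA
CGACGCTCCCACGCGGGTGATATCGAA
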