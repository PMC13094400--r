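# Invalid GRID examples with their defect, tab-separated
999083601612044959	truncated (18 characters)
99904557008102512600	too long (20 characters)
099049639773967774J	single substitution in position 1
999072262549275170A	check character corrupted
999083601612044959!	illegal character
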