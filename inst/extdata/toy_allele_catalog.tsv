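# Toy subset of an IPD-IMGT/HLA release for testing and examples.
# Accession HLA00001 is the official accession of HLA-A*01:01:01:01; all
# other accessions here are SYNTHETIC placeholders in a reserved-looking
# HLA9xxxx range and must not be treated as real database accessions.
# Columns: allele name <TAB> accession [<TAB> key=value metadata]
release	3.57.0
HLA-A*01:01:01:01	HLA00001
HLA-A*01:02	HLA90002
HLA-A*02:01:01:01	HLA90003
HLA-A*02:05	HLA90004
HLA-A*03:01:01	HLA90005
HLA-A*11:01	HLA90006
HLA-B*07:02:01	HLA90007
HLA-B*08:01:01	HLA90008
HLA-B*15:01:01	HLA90009
HLA-B*27:05:02	HLA90010
HLA-B*44:02:01	HLA90011
HLA-C*01:02:01	HLA90012
HLA-C*03:04:01	HLA90013
HLA-C*07:01:01	HLA90014
HLA-C*07:02:01	HLA90015
HLA-DRB1*14:01	HLA90016	ard_identical=HLA-DRB1*14:54
HLA-DRB1*14:54	HLA90017	ard_identical=HLA-DRB1*14:01
HLA-DRB1*01:01:01	HLA90018
HLA-DRB1*03:01:01	HLA90019
HLA-DQB1*02:01:01	HLA90020
HLA-DQB1*06:02:01	HLA90021
HLA-DPB1*04:01:01	HLA90022
HLA-A*01:01:01:02N	HLA90023
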