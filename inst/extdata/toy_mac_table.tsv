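# Toy NMDP Multiple Allele Code table (SYNTHETIC; the real MAC registry is
# maintained by NMDP and is not bundled).
# Columns: code <TAB> '/'-joined expansions [<TAB> '*' marker for
# allele-specific codes whose expansions are full first:second field pairs]
AB	01/02
CD	01/05
EF	02/05
XX	01:01/02:05	*
YZ	07:02/08:01	*
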