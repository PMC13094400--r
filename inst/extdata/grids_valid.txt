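# 20 valid GRIDs under the default mod37_2 scheme (issuer 9990, seeds 1-20)
9990836016120449593
9990455700810251260
999049639773967774J
999072262549275170Q
999018884662259494C
999049732811912470I
9990926195772775799
999036169601225537C
999045722414928580O
999089675627969177G
999091780454564261T
9990196441711859965
9990724955372096647
9990883390824209608
999049185048350446G
999007330927582477P
999017066695009573F
999090158388530174L
999095241820533774C
999057181828713840*
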