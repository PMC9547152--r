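box	start	end
C	5	11
D_prime	26	29
D	54	57
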