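# Absolutist dictionary: 19 words denoting totality of magnitude or
# probability without nuance, validated by a five-judge expert panel.
# False-positive phrase patterns (negation / qualifier / salutation) follow.
absolutely
all
always
complete
completely
constant
constantly
definitely
entire
ever
every
everyone
everything
full
must
never
nothing
totally
whole
~not completely	negation
~almost completely	qualifier
~hello everyone	salutation
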