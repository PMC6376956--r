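# SYNTHETIC STAND-IN nonabsolutist (nuance) dictionary, 43 words of which
# 21 are tagged extreme. The published nonabsolutist word list is not
# redistributable here; this stand-in keeps the documented exemplars
# (rather, somewhat, likely, very, really, anything, need, needed) and pads
# with generic nuance/intensifier vocabulary. For tests and examples only.
rather
somewhat
likely
probably
possibly
perhaps
maybe
occasionally
sometimes
often
usually
generally
mostly
partly
fairly
moderately
slightly
relatively
anything
need
needed
might
very	extreme
really	extreme
extremely	extreme
incredibly	extreme
hugely	extreme
immensely	extreme
massively	extreme
intensely	extreme
remarkably	extreme
exceptionally	extreme
extraordinarily	extreme
tremendously	extreme
enormously	extreme
severely	extreme
deeply	extreme
strongly	extreme
highly	extreme
vastly	extreme
seriously	extreme
majorly	extreme
overwhelmingly	extreme
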