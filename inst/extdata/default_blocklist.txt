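# Compounds deleterious to health or clinically unusable, removed from
# enrichment hit lists by default. Matching is case-insensitive against
# chemical id and display name.
particulate matter
ozone
asbestos
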