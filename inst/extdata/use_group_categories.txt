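# The eight curated use-group categories. Edit to extend.
Industrial Chemical
Pesticide
Biocide
Pharmaceutical
Drug of abuse
Natural
Food additive
Metal
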