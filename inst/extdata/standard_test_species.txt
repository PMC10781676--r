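# Standard test species whitelist used in species_selection =
# "standard_test_species" mode. One Latin name per line; edit freely.
# Seeded with OECD standard acute test species for crustaceans and fish.
Daphnia magna
Daphnia pulex
Ceriodaphnia dubia
Americamysis bahia
Gammarus pulex
Danio rerio
Pimephales promelas
Oncorhynchus mykiss
Oryzias latipes
Lepomis macrochirus
Poecilia reticulata
Cyprinus carpio
Gasterosteus aculeatus
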