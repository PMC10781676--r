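# Broad (system-level) mode-of-action vocabulary: 32 categories.
# Illustrative defaults - the full vocabulary travels with a curated
# catalog; replace this file to match yours.
Neuroactive
Neuromuscular system
Endocrine
Cardiovascular system
Antibiotic
Antiviral
Antifungal
Antiparasitic
Anti-inflammatory
Analgesic
Immune system
Respiratory system
Gastrointestinal system
Metabolism
Cell division inhibition
Nucleic acid damage
Protein synthesis inhibition
Lipid biosynthesis inhibition
Fatty acid biosynthesis inhibition
Amino acid biosynthesis inhibition
Carotenoid biosynthesis inhibition
Cell wall synthesis inhibition
Cell membrane disruption
Photosynthesis inhibition
Synthetic auxin
Plant growth regulation
Mitochondrial respiration inhibition
Oxidative stress
Alkylating agent
Chelating agent
Narcosis
Reproductive system
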