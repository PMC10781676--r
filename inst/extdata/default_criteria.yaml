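# Default per-BQE selection criteria (the shipped study settings).
# Values here mirror the package defaults; copy and edit for custom runs.
criteria:
  Algae:
    species_selection: all
    effects: [MOR, GRO, POP, REP, MPH, DEV]
  Crustacean:
    species_selection: standard_test_species
    effects: [MOR, GRO, POP, REP, MPH, DEV, ITX]
  Fish:
    species_selection: standard_test_species
    effects: [MOR, GRO, POP, REP, MPH, DEV]
# shared settings (package defaults, repeated here for reference):
#   dosing_group: water_concentration
#   duration_d: [d, dph, dpf];  duration_h: [h, ht, hph, hpf, hv]
#   duration_m: [mi]
#   min_d: 0; max_d: 5; min_h: 0; max_h: 120; min_m: 0; max_m: 7200
#   habitat: Water
#   quantile: 0.05
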