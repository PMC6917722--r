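# scFOS: equal-mass GF2/GF3/GF4 split; molar masses are average GF(n)
# formula weights (g/mmol). Override when calibrating against a measured
# supplement composition.
name: scFOS
horizon_hours: 24
flux_scale: 1
components:
  - exchange_id: EX_kestose
    mass_fraction: 0.3333333333333333
    grams_per_mmol: 0.504438
  - exchange_id: EX_kestotetraose
    mass_fraction: 0.3333333333333333
    grams_per_mmol: 0.666579
  - exchange_id: EX_kestopentaose
    mass_fraction: 0.3333333333333334
    grams_per_mmol: 0.82872
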