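# Inulin as a single average polymer of degree of polymerization 10.
name: inulin
horizon_hours: 24
flux_scale: 1
components:
  - exchange_id: EX_inulin
    mass_fraction: 1.0
    grams_per_mmol: 1.801566
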