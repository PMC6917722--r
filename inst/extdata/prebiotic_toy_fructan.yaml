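# Toy fructan used by the bundled toy models: 1 g maps to an uptake bound
# of 1 flux unit (1 g/mmol over a 1 h horizon).
name: toy-fructan
horizon_hours: 1
flux_scale: 1
components:
  - exchange_id: EX_fructan
    mass_fraction: 1.0
    grams_per_mmol: 1.0
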