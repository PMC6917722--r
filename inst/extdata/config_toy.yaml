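# End-to-end toy run: FP-like co-model, toy fructan, 0-10 g dose grid.
toy:
  profile: fp
prebiotic: toy-fructan
dose_grid: {from: 0, to: 10, points: 21}
dose: 5
tracked_reactions: [H_HMGS, EX_d25_lu]
output_dir: lumenfba_out
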