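# Toy western diet: glucose allowance into the lumen, everything else closed.
name: toy-western
bounds:
  EX_glc_lu: [-3, 0]
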