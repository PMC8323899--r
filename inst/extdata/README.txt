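Synthetic example data (no experimental provenance):

  toy_complex.pdb      two-chain pseudo-protein complex,
                       generated by make_toy_complex(6, 12, seed = 42)
  toy_complex_fmo.log  matching pseudo-FMO pair-interaction table,
                       generated by make_toy_pie_table(..., energy_scale = 5,
                       noise_sd = 0.5, seed = 43)

Regenerating with the same calls reproduces the files byte-for-byte.
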