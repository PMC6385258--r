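# Ligand-receptor kinetic rate constants for EGF-EGFR binding.
# The 4C preset approximates cold-block conditions: association is 100x
# slower and dissociation 20x slower than at 37C, and internalization is
# negligible on ice.
presets:
  37C:
    k_on: 1.03e+6    # M^-1 s^-1, EGF + EGFR -> EGF|EGFR
    k_off: 5.67e-03  # s^-1, EGF|EGFR -> EGF + EGFR
    k_int: 5.00e-04  # s^-1, EGF|EGFR -> internalized complex
  4C:
    k_on: 1.03e+4
    k_off: 2.84e-04
    k_int: 0.0
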