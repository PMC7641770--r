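# Covalent-modification candidates for mass-shift stoichiometry.
# Residue mass = free molecule minus one water for condensation adducts
# (AMP); phospho and acetyl are given as the net mass added to the
# protein. Average and monoisotopic scales; extend by appending rows.
name	formula	residue_mass_avg	residue_mass_mono
AMP	C10H12N5O6P	329.2088	329.0525
acetyl	C2H2O	42.0370	42.0106
phospho	HPO3	79.9788	79.9663
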