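# Small-molecule candidates for PDE cleavage-product identification.
# Average masses (Da) computed from the molecular formulas with IUPAC
# standard atomic weights; extend by appending rows.
name	formula	mass_avg
5'-AMP	C10H14N5O7P	347.2238
5'-CMP	C9H14N3O8P	323.1978
5'-UMP	C9H13N2O9P	324.1818
5'-GMP	C10H14N5O8P	363.2228
adenosine	C10H13N5O4	267.2450
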