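---
title: "Methods: motif-based TA mining and adenylylation mass inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: motif-based TA mining and adenylylation mass inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hepnmnt)
```

This vignette documents the models, parameter choices and numerical
decisions behind the package, and what its synthetic-data validation
does and does not demonstrate.

## The biological problem

HEPN/MNT is a widespread prokaryotic toxin–antitoxin (TA) module. The
toxin is a HEPN-domain RNase whose active site carries the conserved
motif RX₄HXY; the antitoxin is a minimal nucleotidyltransferase (MNT)
with the catalytic motif GSX₁₀DXD. The antitoxin inactivates the toxin
by transferring AMP moieties onto a conserved tyrosine (the terminal Y
of the toxin motif) — in the characterised *Shewanella oneidensis*
system, three consecutive AMPs. Two analyses follow from this biology:

1. **Mining**: find genomes encoding an RX₄HXY protein next to a
   GSX₁₀DXD protein, classify the pairs by Pfam family, and census
   their prevalence per taxon.
2. **Mass inference**: detect the modification on the protein — the
   PDE-released product (5′-AMP, 347.22 Da average mass) and the
   intact-mass shift (n × 329.21 Da per AMP residue).

## Motif model

Motif text follows a compact PROSITE-like grammar: letters are exact
residues, `X` is any residue, `[ACD]` a residue set, an integer or
`(min,max)` suffix repeats the preceding element. The three motifs the
package ships are `RX4HXY`, `GSX10DXD` and the general HEPN RNase motif
`RX(4,6)H`.

Two scanning modes are provided, because consensus strings and
alignment-derived profiles answer slightly different questions:

* **Exact mode** (`scan_pattern`): every window satisfying the pattern
  is reported, including overlaps; for ranged repeats every distinct
  (start, end) is reported once. Ambiguity codes (B, Z, J, U, O, X) in
  input sequences satisfy `X` positions but never a specific-residue
  position — a conservative rule that cannot create a motif call out of
  an ambiguous residue.
* **PWM mode** (`pwm_scan`): a position weight matrix is built from
  matched sites with a background-weighted pseudocount,
  `log2(((n_a + p·b_a)/(n + p))/b_a)`. P-values are *exact* under the
  i.i.d. background model, computed by dynamic-programming convolution
  of the column score distributions after scaling scores by 1000 and
  rounding to integers. Reported hit scores are the discretized scores
  divided by 1000, so score order and p-value order agree by
  construction. The 1/1000-bit granularity changes p-values by far less
  than any decision threshold in use; exhaustive enumeration over all
  20^k sequences for k ≤ 4 agrees to 10⁻⁹ (tested).

The default scanning background is the residue composition of the
scanned sequence set (`sequence_background`); tests use the uniform
1/20 background, under which the information content of an invariant
column is log₂20 ≈ 4.32 bits.

## Neighborhood pairing and classification

"Neighboring genes" is operationalised as: same contig, locus-rank
distance ≤ 1, intergenic gap ≤ 500 bp, any strand — the arrangement of
the characterised system (antitoxin immediately upstream of the toxin)
and of typical TA operons. All three knobs are configurable
(`pair_config`). Genes are ranked by ascending start within each
contig; GFF3 coordinates (1-based inclusive) are converted to 0-based
half-open internally.

Candidate toxins are proteins with ≥ 1 RX₄HXY hit **plus** PF05168
family members, which by definition lack the motif (Class II); candidate
antitoxins are proteins with ≥ 1 GSX₁₀DXD hit. Each gene joins at most
one pair: candidates are assigned greedily, nearest rank first, ties
toward the upstream antitoxin, then leftmost. This prevents
double-counting in the census; it is a maximal matching under the
constraints but deliberately *not* a globally maximum matching — in the
rare alternating arrangement toxin–antitoxin–toxin–antitoxin, the
upstream-preference tie-break is honoured before pair count, which
mirrors how operons would be read.

Class labels require both kinds of evidence jointly: Class I = toxin in
PF01934/PF08780 *and* carrying RX₄HXY, antitoxin in PF01909 *and*
carrying GSX₁₀DXD; Class II = toxin in PF05168 with *zero* RX₄HXY hits,
same antitoxin condition. The stricter conjunction (family *and* motif)
is used rather than family alone; a PF05168 toxin that does carry the
motif fits neither definition and is emitted as unclassified with an
explicit flag, so such borderline cases are visible rather than
silently absorbed. The census reports, per taxon and class, total
pairs, mean per genome, and % genomes with ≥ 1 pair; genomes without
pairs count in every denominator.

## Mass model

Masses are computed from elemental composition with IUPAC standard
atomic weights (average scale) or most-abundant-isotope masses
(monoisotopic). The average scale is the default throughout: the
experimental quantities this pipeline interprets (intact-protein
deconvolutions, LC–MS product masses such as 347.6 Da) are
average-mass-scale values. One AMP residue — free 5′-AMP minus the
water lost in phosphodiester condensation — is C₁₀H₁₂N₅O₆P = 329.21 Da
average (329 at integer precision), 329.05 monoisotopic.

`identify_small_molecule` matches an observed mass against a candidate
table within a tolerance (default 0.5 Da, the scale of LC–MS accuracy
for these analytes) and returns *ambiguous* whenever more than one
candidate fits — it never silently picks the nearest.

`infer_stoichiometry` enumerates all count vectors over the candidate
modifications with total ≤ `max_total` (default 10) and keeps those
within tolerance (default 1.5 Da for intact-protein shifts, where
deconvolution error dominates). Among feasible solutions it prefers the
smallest total count (parsimony), then the smallest |residual|, then a
deterministic name-order tie-break. The signed residual is always
reported: for the canonical 987.45 Da shift the three-AMP prediction is
987.63 Da, leaving a −0.18 Da instrument-scale residual that the
tolerance absorbs but the output does not hide.

## Charge-ladder deconvolution

Electrospray puts a protein of neutral mass M at m/z = (M + z·m_p)/z
for a ladder of charge states z (protonation only, positive mode;
default z = 5–30, instrument range m/z 600–2000). Instead of a
maximum-entropy deconvolution, the package uses a deterministic grid
scorer, chosen for reproducibility and testability on the few-species
spectra this pipeline targets: for each candidate mass on a grid
(default step 0.1 Da) it sums the linearly interpolated spectrum
intensity over all charges in range, takes local maxima above a
noise-adaptive threshold (median + 5·MAD of the score track, but at
least 25% of the maximum), and refines each by parabolic interpolation
of the three surrounding grid points.

Plain ladder scoring has a known artifact: harmonic ghosts. A candidate
at M/2 aligns exactly with every even-charge peak of M (z ↔ 2z), and
rational multiples like 2M/3 align with charge subsets, producing
spurious maxima at up to half the true score. Each candidate is
therefore also scored for *charge support* — the fraction of its
visible charge states carrying intensity (≥ 5% of the median aligned
intensity). A real species has support ≈ 1; ghosts align with only a
subset (≤ ~0.6). Candidates below `min_support = 0.8` are discarded.
On noise-free synthetic single-species spectra the refined mass is
within ~10⁻³ Da of truth; at 1% multiplicative intensity noise, within
~0.01 Da — comfortably inside the 0.5 Da acceptance band the tests
assert.

## Synthetic data: what it emulates, and what it does not

`generate_genomes` emits the full input universe — protein FASTA, GFF3,
domain and taxon tables — with ground truth. Defaults describe a
desk-scale study: 50 genomes across four taxa (40% Proteobacteria, 20%
each Firmicutes, Actinobacteria, Euryarchaeota — prevalence of the
module is highest in Proteobacteria), 20 genes per genome, one Class I
and one Class II pair per genome, Swiss-Prot-like background residue
frequencies, intergenic gaps uniform on 20–200 bp (within the 500 bp
pairing limit), protein lengths uniform on 80–200 aa (both motifs fit
with room to spare). Background proteins are resampled until they
contain neither signature motif, so the background false-positive rate
is zero by construction; planted motif instances have their X positions
drawn from the background so sites vary realistically. Four decoy
kinds each violate exactly one pairing rule — lone toxin motif, lone
antitoxin motif, pair at rank distance 2, and an RX₄H motif lacking the
terminal Y — making each rule independently falsifiable. Blocks are
separated by at least one background gene so decoys cannot accidentally
sit next to a planted partner. A single seed fans out to per-genome
subseeds (`seed·1009 + g mod 2³¹−1`), so outputs are byte-identical per
seed and each genome independently reproducible.

What passing on this generator does **not** show: real genomes have
non-i.i.d. residue composition, overlapping and nested operons,
annotation errors, motif variants that drift from the consensus, and
Pfam labels with their own error modes. Exact-pattern mining is exact
here because the truth *is* the pattern; on real data the PWM mode with
its p-value threshold, and the configurable adjacency knobs, are the
instruments of sensitivity/precision trade-off. Likewise
`generate_spectrum` models Gaussian peaks and multiplicative noise
only — no isotope envelopes, adducts, baseline drift or
chromatographic effects — so deconvolution accuracy on real spectra
will be poorer than the synthetic figures.

## Problem sizes and determinism

The shipped tests run the full pipeline at the study scale stated
above (50 genomes, 100 planted pairs; 100 random deconvolution masses;
exhaustive PWM enumeration up to width 4; 1,000 random 200-mers against
an independent window-checking oracle) in a few minutes on one core.
All stochastic tests fix their seeds; degenerate inputs (empty
sequences, empty peak lists, zero shifts, genomes without coding genes)
are exercised explicitly and either return well-defined empty results
or fail with named errors.

## Known limitations

* Pfam domain labels are consumed as an input table; the package does
  not run HMM searches.
* The deconvolution scorer assumes protonation as the only charge
  carrier and is not designed for dense many-species mixtures.
* Exact-pattern scanning has no notion of motif strength; use the PWM
  mode when ranking or thresholding matters.
* The one-pair-per-gene greedy can under-pair pathological alternating
  arrangements (see above); such cases did not arise in any simulated
  genome, and the flag columns make manual review possible.
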