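---
title: "Designing and quantifying species-specific MRM assays with mrmarker"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and quantifying species-specific MRM assays with mrmarker}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmarker)
```

## The problem and the model

Meat adulteration — substituting or diluting a declared meat with a cheaper
species — is detected most robustly at the protein level, because peptides
survive cooking and processing that degrade DNA. The assay this package
supports is multiple reaction monitoring (MRM) on a triple-quadrupole
instrument: for each species in a panel (here typically beef, pork,
chicken, duck, lamb), a handful of *species-specific tryptic peptides* is
monitored as transitions (precursor m/z, product m/z, collision energy).
Presence of a species is a detection call on its markers; its mass fraction
is read off a linear standard curve built from binary mixtures.

`mrmarker` covers the computational chain: digestion of per-species
proteomes, uniqueness screening, transition design, and calibration-based
quantification. Everything downstream of sequence databases and upstream of
the instrument is implemented; everything that needs real spectra
(abundance, signal-to-noise, retention time) enters only as empirical
metadata supplied by the user.

## In-silico digestion

Trypsin cuts after K or R. Two conventions are deliberate defaults:

- **Proline rule ON**: K/R followed by P is not cut. This is the standard
  in-silico convention; it is configurable because database search engines
  differ.
- **Protein termini count as tryptic.** A peptide at the protein
  C-terminus need not end in K/R to be "fully tryptic". The built-in
  reference panel contains such a peptide (NLVHIITHGEEKD, a lamb marker
  ending in D), which is only admissible under this convention.

Missed cleavages are enumerated exactly: with `max_missed = m`, every
concatenation of up to `m + 1` adjacent fragments is emitted, so with *s*
internal sites the peptide count before length filtering is
$\sum_{k=0}^{\min(m,s)} (s+1-k)$. The default `max_missed = 2` matches
common database-search settings. Ambiguous residues (B, J, O, U, X, Z) have
undefined monoisotopic masses; peptides containing them are flagged and
barred from marker candidacy but kept in the index so cross-species
coverage is not silently reduced.

Initiator-methionine clipping is *not* applied: without annotation there is
no way to know which sequences are unprocessed precursors, so guessing
would create phantom termini.

## Mass arithmetic

Monoisotopic residue masses are carried to six decimals; water is
18.010565 Da and the proton 1.007276 Da. A peptide's neutral mass is the
residue sum plus water plus modification deltas; the precursor at charge
*z* is $(M + z\,m_p)/z$; fragment ions follow the b/y convention
($y_n$ keeps the C-terminal *n* residues plus water). Two modifications are
built in: carbamidomethyl-Cys (+57.02146 Da), applied as a *fixed*
modification because alkylation with iodoacetamide is part of standard
sample preparation, and Met oxidation (+15.99491 Da) as a variable one. The
cysteine-bearing peptide in the reference panel (ECQTLVSDVDYR) matches its
printed precursor only under carbamidomethylation, which anchors that
default.

Internally every fragment computation goes through a per-residue mass
vector with mod deltas added at their positions, so the b/y complementarity
identity $b_i^{1+} + y_{L-i}^{1+} = M + 2m_p$ holds to machine precision;
the test suite asserts it across random peptides at every position.

Defaults follow tryptic MRM practice: precursors at 2+, products at 1+.
All 14 mass-verifiable rows of the built-in panel are consistent with
those charge states. One panel row (FLEELLTTQC) has a printed precursor
about 135 m/z above anything computable from its printed sequence under
any standard Cys modification; it is flagged `mass_verifiable = FALSE` and
excluded from mass checks (its CE and length still verify). The likely
explanation is a truncated or mistyped published sequence.

## Marker screening

Uniqueness is decided on canonical keys with **I/L equivalence on by
default**: leucine and isoleucine are isobaric and indistinguishable on a
triple quadrupole, so a peptide whose only distinction from another
species' peptide is an I/L swap must not be called specific. Keys map both
residues to a common symbol; turning equivalence off provably only enlarges
the marker set (a monotonicity the tests assert).

Uniqueness is assessed within *tryptic space* — the digested peptide sets —
mirroring how markers are screened from observed digests. An optional
strict mode additionally rejects candidates occurring as substrings of any
other species' proteins, guarding against homologous context that a
different digestion parameterization would expose.

The default marker filter encodes the published panel's observed
properties: 9–17 residues, zero missed cleavages, tryptic termini.
Methionine is excluded by default (oxidation splits the signal between two
masses); cysteine is allowed because carbamidomethylation is fixed and
complete. Abundance and signal-to-noise are *not* computable from sequence:
`rank_markers()` accepts an observed-intensity table and only orders
candidates with it — an honest representation of what in-silico screening
can and cannot decide.

Real-database marker counts are deliberately out of scope: they depend on
database release, isoform redundancy and search settings, so the package
demonstrates correctness on synthetic fixtures with planted ground truth
instead.

## Transition design

Collision energy is modeled as the vendor-standard charge-dependent linear
ramp $CE = a\,(m/z)/100 + b$. The default 2+ ramp, slope 3.1 V per
100 m/z with offset +1.0 V, reproduces all fifteen collision energies of
the built-in panel exactly after rounding to one decimal — including the
mass-unverifiable row, whose CE follows its *printed* precursor. No 3+
ramp is anchored by the panel, so none is defaulted; configuring one is a
one-line config entry.

Which product ion responds best cannot be predicted from sequence (the
panel's indices range over y7–y13), so the default selection mode is
`empirical`: the caller names the observed best product per peptide. The
`rank` mode emits the top-k high-m/z y-ions inside the instrument window
(default 300–1400 m/z, index ≥ 3) as a starting panel for method
development, ties broken by ascending index. Retention times are copied
from input, never predicted.

Exports are vendor-neutral CSV with six decimals on m/z, one on CE, three
on RT; the round trip is lossless at that precision.

## Quantification

The calibration model is ordinary least squares of raw transition intensity
on target mass fraction, per peptide — matching assays whose published
curves are simple linear fits without internal-standard normalization.
Replicates are averaged per level by default (configurable). Inverse
prediction divides out the slope and propagates the residual standard
deviation into a first-order interval; estimates are clipped to [0, 1] with
an explicit flag rather than silently truncated. A slope below 1e-12 in
absolute value raises an error rather than returning a wild estimate.

Panel-level calls use the median across a species' marker estimates with
the median absolute deviation as spread; the median tolerates one
interfered transition per panel, which is the practical reason assays carry
several markers per species.

The detection limit uses the calibration-based definition
$LOD = 3.3\,\sigma_{blank}/slope$, and per-transition detection thresholds
default to $mean(blank) + 3\,sd(blank)$. These are stated conventions, not
fitted quantities: published assays demonstrate ~1% detectability
empirically without giving a formula, so the package adopts the standard
ICH-style rule and verifies *behaviour at the definitional boundary* by
simulation (with noise calibrated so the rule gives LOD = 0.01, 1% spikes
are detected in well over half of seeded replicates).

## The synthetic-data generator

`make_toy_proteomes()` builds per-species proteomes as concatenations of
full tryptic units: background chunks and planted peptides. Design choices:

- Planted peptides are drawn to satisfy the default marker filter by
  construction: 9–17 residues, terminal K/R, no internal cleavage site, no
  methionine, never starting with proline (which would suppress the
  upstream cut and fuse the peptide to its neighbour).
- Background chunks are built so they can *never* pass the marker filter:
  short bodies digest to under 9 residues and long bodies carry a
  methionine. This makes ground-truth recovery exact — the screen's output
  equals the planted set — which is what gives fixture tests their force.
- Background chunk lengths are mixed so the combined K/R frequency lands
  near the natural ~11%; residue usage is otherwise uniform. This is
  simplicity over realism: no inter-species homology, no codon-level
  structure.
- Collisions (a "unique" peptide whose key appears in another species,
  including inside background) are resolved by redrawing, bounded at 100
  attempts; everything is reproducible from the seed.

What passing fixture tests does **not** show: behaviour on real proteomes
with massive cross-species homology, isoform redundancy, or real intensity
distributions. The generator validates the logic, not the biology.

`simulate_mixture_intensities()` produces
$I = slope \cdot fraction + intercept + N(0, \sigma)$, floored at zero,
replicates independent, seeded — the linear-response assumption underlying
the calibration module, with additive Gaussian noise as the simplest
honest error model.

## Numerical choices and problem sizes

- m/z reported to six decimals; test comparisons against published values
  use 0.01 m/z to absorb mass-table rounding differences between sources.
- CE compared at 0.05 V before rounding, exact after rounding to one
  decimal.
- Fragment annotation tolerance defaults to 0.02 m/z (unit-resolution
  quadrupole practice is looser; the default is deliberately tight because
  the annotator is also used as a verification tool).
- Fixture sizes: digestion oracles run on proteins of 25–150 residues;
  uniqueness oracles on 5 species × 20 proteins; calibration coverage on
  100 seeded simulations of the six-level, three-replicate design; LOD
  boundary behaviour on 200 seeded replicates. These sizes make brute-force
  oracles exact and fast while exercising every code path.

## Known limitations

- No retention-time prediction, fragment-intensity prediction, dwell-time
  scheduling, or vendor binary method export.
- Only b/y singly/multiply protonated ions; no a/c/x/z series, neutral
  losses, or isotope envelopes; monoisotopic masses only.
- Uniqueness is only as good as the supplied FASTA: absent species or
  incomplete proteomes cannot veto a marker.
- The linear no-internal-standard calibration assumes matrix effects are
  constant across the dilution series; the package provides no
  matrix-effect correction.
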