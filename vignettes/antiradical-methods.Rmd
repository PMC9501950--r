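---
title: "Methods: conceptual-DFT antiradical profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conceptual-DFT antiradical profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(antiradical)
```

## The model

Electron-transfer radical scavenging can run in either direction: an
antiradical `aox` may donate an electron (`aox + R· → aox⁺ + R⁻`) or accept
one (`aox + R· → aox⁻ + R⁺`). Everything this package computes derives from
the two vertical energy differences that quantify those channels,

* ionization potential `I = E(cation) − E(neutral)` — low I means easy
  oxidation, hence a good donor;
* electron affinity `A = E(neutral) − E(anion)` — high A means a good
  acceptor; a *negative* A (vertical attachment to a metastable anion) is
  physically legitimate and handled as a notice, never an error.

All species energies are total electronic energies in hartree at the
neutral geometry; the package converts to eV with a single configurable
factor (27.211386 eV/hartree). The pipeline consumes energies or
pre-computed I/A values; it never runs quantum chemistry.

From I and A (eV) the global reactivity descriptors follow: hardness
`η = (I − A)/2` (stability against charge transfer), softness `S`
(its reciprocal measure), electronegativity `χ = (I + A)/2`, chemical
potential `μ = −χ`, and the electrophilicity index `ω`. The asymmetric
charge-transfer powers are

$$\omega^- = \frac{(3I + A)^2}{16(I - A)}, \qquad
  \omega^+ = \frac{(I + 3A)^2}{16(I - A)},$$

with the algebraic identity `ω⁻ − ω⁺ = χ` (tested to 1e-9 eV on 10⁴ random
pairs). The donor–acceptor map plots `Rd = ω⁻/ω⁻(Na)` against
`Ra = ω⁺/ω⁺(F)`: a good antioxidant has low Rd and low Ra, a good
anti-reductant high Ra.

## Conventions: why there are two

Descriptor tables in the applied literature are frequently produced by
evaluating `ω = μ²/2` and `S = 1/(2η)` with the energies still in atomic
units and reporting the bare number in an "eV" column. The result differs
from the eV-scale literature definitions by fixed powers of the conversion
factor F:

| quantity | `"standard"` | `"replication"` |
|---|---|---|
| softness | `1/(2η)` (eV⁻¹) | `F²/(2η)` |
| electrophilicity | `μ²/(2η)` (eV) | `μ²/(2F)` |

`"replication"` reproduces such published tables bit-faithfully (e.g.
I = 9.74, A = 3.06 gives ω = 6.40²/54.423 = 0.75); `"standard"` gives the
textbook values (the same inputs give ω = 6.13 eV). The identities
`χ = −μ` and `η = (I − A)/2` are convention-independent. Every output row
carries its convention tag and the table writers refuse to mix tags:
silently comparing a replication S (≈ 105 for η ≈ 3.5 eV) with a standard
S (≈ 0.14 eV⁻¹) is the one mistake this design makes impossible.

## DAM anchors and sector rules

The default references are experimental atomic values — Na I = 5.139 eV,
A = 0.548 eV (ω⁻ ≈ 3.470 eV) and F I = 17.423 eV, A = 3.401 eV
(ω⁺ ≈ 3.402 eV) — stored as configurable data, not hard-coded powers.
They are validated by an internal oracle: published ω⁻/Rd and ω⁺/Ra ratios
across a five-compound panel pin the anchor powers to a fraction of a
percent (per-row agreement is limited only by the 2-dp rounding of the
printed values).

Published maps do not standardize sector geometry, so two labels are
emitted side by side rather than guessing one intent:

* **absolute** — quadrants against boundaries Rd = 1, Ra = 1 (the
  anchors), boundary values assigned to the lower side;
* **relative** — "donor-leaning" when Rd does not exceed the dataset
  median and Ra < 1, "acceptor-leaning" otherwise. This captures the
  common qualitative reading in which a whole panel of modest donors
  (Rd ≈ 1.1–1.2, Ra ≈ 0.1) is called the good-antioxidant group while the
  standards (Ra ≈ 1) form the acceptor group; the median tie goes to the
  donor side so that a compound sitting exactly at the panel median is not
  expelled from its own group.

Compounds with degenerate I ≤ A abort their own DAM placement only; the
rest of the table proceeds and the failure is recorded.

## Assay statistics

Percent inhibition uses the standard DPPH definition
`100·(A_control − A_sample)/A_control` (the methods literature cites the
assay but rarely prints the formula). IC50 defaults to log-linear
interpolation between the two observations bracketing 50% — the
fewest-assumptions estimator, which refuses to extrapolate unless asked.
The logistic alternative fits
`y = bottom + (top − bottom)/(1 + (IC50/c)^hill)` by least squares; since
the response is percent inhibition — anchored at 0 in the absence of
compound and saturating at 100 — the asymptotes are fixed at 0/100 by
default (the normalized-response logistic). On short dilution series this
matters: at n = 8 concentrations with 2% multiplicative noise the
constrained fit's median |IC50 bias| is ≈ 1.4%, while freeing all four
parameters roughly triples it. `fix_asymptotes = FALSE` restores the free
4PL for data that are not percent-normalized.

Descriptor–activity agreement is reported as a Pearson battery: r, the
least-squares line and per-compound residuals for *every* available
descriptor (I, A, Rd, Ra, ω⁻, ω⁺, HOMO, …), because the single "in silico
value" behind a published correlation is often unidentified. No particular
published r is asserted anywhere in the test suite for that reason.

## The synthetic generator: what it emulates and what it does not

`gen_energy_triplet()` inverts the I/A definitions around an arbitrary
neutral base (`E_cation = base + I/F`, `E_anion = base − A/F`); only
differences enter the pipeline, so the base is free and the round-trip is
exact by construction (verified to 1e-9 eV, and to 1e-6 relative through
the full file-I/O path). Energies carry no noise: the in silico side of
the workflow is deterministic. Assay curves are Hill logistics
`100/(1 + (IC50/c)^h)` with multiplicative Gaussian noise
`y·(1 + N(0, σ))`, σ defaulting to 2% — a realistic microplate
photometric error — on an 8-point two-fold dilution series centered on
each true IC50, clamped to [−10, 110] with clamping counted. One integer
seed drives everything; per-curve seeds are derived from it and the global
RNG state is restored afterwards.

The `"flavanones"` preset states the generator's world: five gas-phase
compounds and three methanol rows with published I/A as targets, three
published HOMO energies, and five published IC50s (4.53–548.72 ppm) as
ground truth. What the generator does *not* emulate: correlated QM errors
between charge states, basis-set or functional sensitivity, solvent-model
artifacts, plate-position or replicate structure in the assay. A green
round-trip test therefore establishes that the *arithmetic* of the
pipeline is right — not that a DFT protocol or an assay design is.

## Numerical choices

* Hartree→eV factor 27.211386, one constant shared by every
  convention-sensitive formula.
* A value printed as `-0.00` parses to exactly 0 with the sign surfaced as
  a record note (tiny negative affinities are often rounded to zero
  upstream; the discrepancy is reported, not hidden).
* HOMO ranking breaks ties lexicographically by compound id —
  determinism for testing; ties in either HOMO or I count as compatible
  in the concordance check.
* Canonical table writer: fixed column order, shortest round-tripping
  decimals, LF endings; read→write is byte-stable.
* Interpolation IC50: exact 50% observations are returned verbatim;
  otherwise interpolation is linear in log10(concentration).
* Degenerate inputs (I ≤ A, constant response curves, zero-variance
  correlations) are per-item errors, isolated by the pipeline and
  recorded in the bundle's failure table.

## Known limitations

* No parsing of QM program logs, no structure handling, no molar units
  (IC50 stays in ppm; molecular weights are out of scope).
* The replication convention reproduces published tables only to their
  printed rounding; second-decimal drifts of one unit occur where the
  upstream table was computed from unrounded I/A (documented per-value in
  the acceptance suite).
* The frontier-orbital stage ranks; it never substitutes orbital energies
  for the energy-difference I and A (no Koopmans estimation).
* LUMO energies are optional everywhere; gap features degrade gracefully
  because many published studies print HOMO values only.
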