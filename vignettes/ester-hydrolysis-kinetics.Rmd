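---
title: "Comparative kinetic stability of arsenate and phosphate esters"
author: "esterkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative kinetic stability of arsenate and phosphate esters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(esterkin)
```

## The scientific question

Arsenate (AsO4^2-) is a structural mimic of phosphate (PO4^2-): it carries
the same charge at physiological pH, rides the same transporters, and is
incorporated by the same enzymatic machinery into phosphate-ester
biomolecules — from simple monoesters such as pyrophosphate and
ribose-1-phosphate up to the phosphodiester backbone of DNA. The biological
question is not whether arsenoesters *form* but whether they *survive*:
their hydrolysis by water is dramatically faster than that of the
phosphorus analogues. `esterkin` implements the post-processing side of a
comparative kinetic-stability study of such esters: it takes optimized
reactant and transition-state structures, electronic energies and harmonic
frequencies (the outputs of a quantum-chemistry engine, which is outside
the scope of this package) and turns them into classified species,
geometry-change tables, activation free energies, first-order rate
constants, half-lives and comparative stability ratios.

The rate-determining step modelled throughout is the associative (SN2-like)
attack of a water nucleophile on the central As/P atom, proceeding through
a pentacoordinate, trigonal-bipyramidal transition state with exactly one
imaginary vibrational mode. Hydrolysis is first order in the ester.

## Ester classification

Biological phosphate esters are grouped by how the central atom anchors to
the rest of the molecule, because the anchoring pattern — not the identity
of the conserved attachment site — controls hydrolysis kinetics:

* **Class 1A** — monoester with an `O-P-R` bridge (pyrophosphate /
  pyroarsenate; the ATP/ADP anchoring pattern);
* **Class 1B** — monoester with an `O-C-R` bridge (sugar esters such as
  ribose-1-phosphate);
* **Class 2** — diester with two `O-C` bridges (the nucleic-acid
  backbone).

`classify_ester()` implements this operationally on a perceived bond
graph: find the As/P reaction center (the one bonded to the most oxygens;
ties broken by lowest serial and flagged as ambiguous), walk its oxygens,
and count those bridging to a non-hydrogen heavy atom. One bridge makes a
monoester, two a diester; a phosphorus beyond the bridge gives 1A, carbon
gives 1B or 2. The anionic state is read from the structure's net charge
(−1 mono, −2 di); class 2 diesters exist only in the monoanionic form,
since the diester has a single ionizable oxygen.

## From frequencies to rate constants

**RRHO thermochemistry.** `rrho_corrections()` evaluates the standard
ideal-gas rigid-rotor harmonic-oscillator partition functions at 1 atm:
Sackur–Tetrode translation, classical rotation from the principal moments
of inertia (monatomic and linear cases handled; symmetry number
configurable, default 1), and harmonic vibrations over the real modes.
The thermal enthalpy includes the zero-point energy and the ideal-gas RT
term, and the Gibbs correction is defined as
`H_corr − T·S/1000` exactly (kcal/mol with S in cal mol⁻¹ K⁻¹). For a
transition state the single imaginary mode is excluded from every
statistical sum. No quasi-harmonic raising or flooring of low frequencies
is applied — the simplest faithful treatment, and the one whose inverse is
well defined for the synthetic fixtures. Solvation is assumed to already
be contained in the electronic energies supplied.

**Eyring kinetics.** With the activation free energy
ΔG‡ = G(TS) − G(reactants), transition-state theory gives

$$k(T) = \frac{k_B T}{h\,c^\circ} \, e^{-\Delta G^\ddagger / RT},
\qquad c^\circ = 1,$$

with a transmission coefficient of 1. `eyring_rate()` evaluates this in
log space and keeps `log_rate` alongside `rate_constant`: backbone
diesters sit near k ≈ 10⁻²⁰ s⁻¹ (ΔG‡ ≈ 44 kcal/mol), and ratios across
sixty orders of magnitude must not underflow. `invert_eyring()` is the
closed-form inverse; the two are mutual inverses to better than 1e-10
relative across the full representable range, which is the package's main
self-consistency check against the published rate table. Physical
constants are CODATA 2018 values embedded to full precision
(`physical_constants()`); 1 cm⁻¹ = 2.85914×10⁻³ kcal/mol. The default
temperature is 298 K as printed in the source data; at 2 significant
figures the distinction from 298.15 K is immaterial.

```{r eyring}
dg <- invert_eyring(0.08, temperature = 298)   # pyroarsenate dianion
dg
signif(eyring_rate(dg)$rate_constant, 1)
stability_ratio(5.74e-20, 8.53e-14)            # diester backbone vs sugar ester
```

**Activation strain.** `asm_decompose()` splits the electronic barrier as
ΔE‡act = ΔE‡dist + ΔE‡int: the energy to distort each separated fragment
from its equilibrium geometry to its in-TS geometry, plus the interaction
between the distorted fragments. The default reactant reference is the
separated-fragment sum, under which the additivity identity is exact by
construction; an explicit pre-reaction-complex reference is accepted only
with a mandatory annotation, and the deviation from additivity is then
reported rather than hidden. Energies enter in kcal/mol or hartree with
an explicit unit tag — never inferred.

## Structure handling

Geometries live in a plain S3 container (elements, coordinates in
angstrom, serials, optional PDB-style metadata, net charge, role). XYZ and
PDB v3.3 ATOM/HETATM subsets are read and written; element inference
prefers the PDB element column and falls back to the atom-name convention.
Atom indices are 1-based everywhere; PDB serials are preserved on write.

Bonds are perceived from a single embedded Cordero-type covalent radius
table: atoms bond when their distance is at most `scale` times the radius
sum, with `scale = 1.15` by default — loose enough to survive the 0.01 Å
jitter of the synthetic fixtures, tight enough not to fuse 1,3 neighbours
(2.4 Å apart in a standard chain, versus a 1.75 Å C–C cutoff). All bonds
are single; bond orders are not modelled.

Internal coordinates follow the field conventions: angles in [0, 180],
torsions signed in (−180, 180] with the IUPAC sign, which makes a torsion
invariant — value and sign — under reversing the atom order.
`parameter_table()` assembles reactant-vs-TS comparisons with
`delta = ts − reactant` at full precision (printing rounds to 2
decimals). `kabsch_superpose()` computes the least-squares optimal rigid
transform by SVD with the determinant correction, guaranteeing a proper
rotation; correspondence is an explicit atom pairing, with a helper that
pairs by (residue number, atom name) over heavy atoms by default since
hydrogen placement differs between modelled and crystal structures.
Degenerate inputs (fewer than 3 pairs, collinear reference) raise errors
rather than returning an ill-conditioned fit.

## Two-layer QM/MM partitioning

For strand-sized systems only the reaction region is treated quantum
mechanically. `partition_oniom()` implements the layer-cutting rule: cut
only non-polar bonds between two sp³-hybridized carbons, both of whose
endpoints lie more than four bonds (graph distance) from the reaction
center. Design choices made where the rule leaves freedom:

* *sp³ detection is topological* — a carbon with exactly four neighbours —
  because synthetic and experimental structures need not have idealized
  angles;
* *"more than four bonded atoms away" is applied to both endpoints* of
  the cut bond, the stricter reading, which avoids cutting adjacent to
  the boundary shell;
* *the QM region is minimal*: removing **all** eligible cut bonds at once
  and taking the component containing the center yields the smallest
  admissible region (any admissible region is a union of components of
  that reduced graph and must contain this one), so no search is needed;
  the test suite verifies minimality against brute-force enumeration of
  every cut subset on small graphs;
* *link atoms* are hydrogens placed on the cut-bond axis at 1.09 Å from
  the QM-side carbon, unscaled, since no scaling convention is specified
  for the source model;
* a molecule with no eligible cut bond becomes whole-system QM with a
  warning, not an error — the correct limit for small esters plus water.

The MM layer is flagged frozen by default, mirroring the practice of
constraining the backbone scaffold. `substitute_central_atoms()` performs
the As-for-P backbone edit: elements change in place, coordinates are
untouched by default (bit-exact away from the targets), and an optional
mode lengthens each As–O bond along its axis by the covalent-radius
difference (+0.12 Å), moving only the oxygens of that ester group. An
oxygen bridging two substituted centers receives both displacements; the
result is then only approximate for that bridge, which is documented
rather than silently corrected.

## The synthetic-data generators

The generators replace the quantum-chemistry engine for testing purposes.
They emulate:

* tetrahedral ester reactants and 5-coordinate TS-like structures whose
  *asserted* internal coordinates (central-atom bond lengths and the
  bridging angle, per class and central atom) are the published
  reactant/TS values embedded as construction parameters — so measuring
  the synthetic structure reproduces the published number exactly, while
  every non-asserted coordinate carries 0.01 Å uniform jitter;
* fragment-energy sets whose distortion/interaction decomposition is
  prescribed, with random per-fragment splits (recovery is exact to
  floating-point rounding, ~1e-13 kcal/mol, asserted at 1e-10);
* reactant/TS pairs with prescribed activation free energies: the
  generator computes both RRHO corrections with its own closed-form
  evaluation and solves for the TS electronic energy, so the full
  frequencies-to-ΔG‡ pipeline must reproduce the target to 1e-9;
* simplified sugar–phosphate single strands: a three-carbon sp³ sugar,
  O5'/O3' bridges, a placeholder base nitrogen, and tetrahedral P/As
  centers with two terminal oxygens, laid out as an extended zigzag so
  covalent-radius bond perception recovers exactly the intended
  connectivity, with valid PDB serialization and per-residue bookkeeping.

What they do **not** emulate — and therefore what passing tests do *not*
demonstrate about real systems: physically realistic force fields or
vibrational spectra, base stacking, solvation structure, conformational
flexibility, or counterions. The generators certify the *arithmetic* of
the pipeline against known ground truth, not the chemistry of any real
ester. All generators are pure functions of (parameters, seed): the same
seed gives a bit-identical bundle and the caller's RNG state is left
untouched.

## Numerical choices and degenerate inputs

* Rates are carried as natural-log values internally; scientific-notation
  rendering in reports uses 2–3 significant figures.
* The Eyring pair round-trips to 1e-10 relative; the report builder
  computes every ratio from log rates, so 10⁻²⁰-scale entries divide
  cleanly.
* A negative activation free energy warns (and is recorded in the report
  footnotes) but does not error: barrierless steps are meaningful inputs.
* Contradictory kinetic inputs — both a rate and a barrier, inconsistent
  beyond 0.1 kcal/mol through the round trip — are a hard consistency
  error.
* A single-atom species gets zero rotational terms without error; linear
  molecules are detected from the moment-of-inertia spectrum (smallest
  over largest below 1e-6).
* Ties in reaction-center identification break to the lowest serial and
  are reported as ambiguous, so symmetric species such as pyrophosphate
  analyse deterministically.
* Strand extraction leaves severed termini untouched by default; an
  optional flag caps severed bonds at selected oxygens with hydrogens at
  0.96 Å, since the source model is silent on capping.

## Problem sizes in the test suite

The property suites run at sizes chosen to finish in seconds while still
exercising the claims: 1000 seeded activation-strain fixtures, 10,000
random rigid transforms against the Kabsch optimum, 50
thermochemistry-to-kinetics round trips, 1000 log-spaced rates across 60
decades, brute-force cut-set enumeration on a 20-atom chain and 3-residue
strands, and 4-to-5-residue strands for the partition invariants.

## Known limitations

* The package post-processes electronic-structure results; it computes no
  electronic energies, optimizes no geometries and evaluates no
  force-field terms.
* The superposition validation against a crystal-structure reference
  requires the user to supply both coordinate sets; published
  supplementary geometries distributed as PDF must be extracted by the
  user into XYZ/PDB first.
* Bond perception is purely geometric; exotic valences outside the
  embedded radius table are rejected rather than guessed.
* No tunnelling, variational, or temperature-dependent-barrier
  corrections: the plain Eyring expression is the model, as in the source
  analysis.
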