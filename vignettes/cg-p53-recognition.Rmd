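---
title: "A coarse-grained model of p53 target search and response-element recognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A coarse-grained model of p53 target search and response-element recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(p53cg)
```

## The model

p53 binds DNA as a homotetramer. Each 393-residue subunit carries a folded
DNA-binding core domain (residues 91–289) and tetramerization (TET) domain
(326–356), flanked by the intrinsically disordered N-terminal domain
(1–90) and C-terminal domain (357–393) and joined by a flexible linker
(290–325). The target — a response element (RE) — consists of two 10-bp
half-sites matching RRRCWWGYYY, separated by a 0–21-bp spacer; each
half-site is read by a dimer of core domains, so the RE decomposes into
four 5-bp quarter-sites.

`p53cg` implements a residue-level model of this system and the analyses
that go with it:

* **Protein.** One bead per residue at the Cα position. Folded domains are
  held by a structure-based (Gō) potential: harmonic bonds and angles and
  cosine dihedrals at their native values, plus 12–10 contact terms
  \(U(r) = \varepsilon[5(r_0/r)^{12} - 6(r_0/r)^{10}]\) for native pairs
  (Cα–Cα distance ≤ 6.5 Å, sequence separation ≥ 4 by default; both are
  configuration keys since contact-map conventions differ between
  published parameterizations). Disordered regions get sequence-generic
  statistical local potentials — tabulated virtual-bond-angle and
  virtual-dihedral energies evaluated with C1-continuous (Catmull–Rom)
  interpolation, periodic in the dihedral — and no structure-based
  contacts. The linker additionally carries designated pairwise 12–10
  terms with per-pair strengths (uniform by default, overridable through
  the contact list), standing in for contact-map-optimized pair
  parameters.
* **DNA.** Three beads per nucleotide (phosphate, sugar, base), with the
  5′-terminal phosphate omitted — so an *n*-bp duplex has
  2(3n − 1) beads and 2(n − 1) unit negative charges. Bonds, angles and
  backbone dihedrals take their native values from an ideal straight
  B-form helix (rise 3.38 Å/bp, twist 36°/bp), making the straight duplex
  the exact minimum of the bonded terms; intra-strand stacking and
  Watson–Crick pairing are 12–10 contacts with
  \(\varepsilon_{AT} < \varepsilon_{GC}\). This is a deliberately
  simplified three-site-per-nucleotide model: no solvation term, no
  ion-condensation correction, no sequence-dependent mechanics — the DNA
  serves as a charged, bendable track.
* **Charges and electrostatics.** +1e on Lys, His and Arg (His follows
  the model convention despite its pKa being borderline at pH 7), −1e on
  Asp, Glu and phosphates. Interactions are screened Coulomb
  (Debye–Hückel) at dielectric 78, truncated and shifted at 50 Å
  (≈ 7.5 λ_D at 210 mM, where the interaction is negligible). At the
  production conditions — 300 K, 210 mM monovalent salt — the Debye
  length is `r round(debye_length(300, 0.21, 78), 2)` Å. CTD
  "acetylation" is modelled by zeroing the six CTD lysine charges
  (`neutralize_ctd = TRUE`).
* **Recognition.** Core–RE binding and Core–Core packing are
  structure-based contacts taken from a reference bound complex, with free
  strength parameters `eps_core_re` and `eps_core_core`. The Core–RE
  strength would properly be calibrated against an experimental
  dissociation constant; here its default (1.2 kcal/mol per contact) is
  chosen so the bundled mini Core–RE fixture stays stably bound at 300 K.
* **Excluded volume.** \(\varepsilon_{ev}(\sigma/r)^{12}\) truncated and
  shifted at 2σ, σ the sum of per-kind bead radii, ε_ev = 0.2 kcal/mol.
  Pairs within three bonds, and pairs that already have a contact term,
  are excluded.

## Dynamics

The integrator is BAOAB-split underdamped Langevin dynamics. With friction
γ = 0 it reduces to velocity Verlet and conserves energy (the NVE-limit
test bounds the drift at 10⁻⁴ kcal/mol per 10⁵ steps on a harmonic
dimer); with the production friction γ = 0.02 (reduced ps)⁻¹ at 300 K it
samples the canonical distribution — a harmonic dimer reproduces
⟨(r−r₀)²⟩ = k_BT/k within 2% over 10⁷ steps. Beads listed in the fixed
mask (e.g., the constrained duplex ends) never move. A half-harmonic
spherical wall (default 10 kcal/mol/Å²) implements the container; the
production presets pair a 350 Å radius with 100-bp DNA and 300 Å with
50-bp DNA.

Time is internally a reduced CG unit throughout. Mapping reduced time to
physical time requires an external calibration (e.g., matching a domain
diffusion coefficient); the package stores durations in reduced units and
leaves any mapping factor to the user as metadata.

Thermal noise is generated by a counter-based RNG: a splitmix64-style hash
of (seed, global step, bead, dimension) feeding a Box–Muller pair. Because
the noise depends only on the global step index, restarting from a
checkpoint reproduces the original continuation bitwise — asserted in the
test suite.

Bond energies use the convention \(U = k(r-r_0)^2\) (no ½), so a "spring
constant k" in the ½-convention corresponds to `kf = k/2` here; the
umbrella bias uses the ½ convention explicitly (below).

## Replica-exchange umbrella sampling and WHAM

The binding reaction coordinate is the distance between two bead-group
centroids — by default an unbound Core and its RE quarter-sites, both
configurable. Each window *i* applies \(U_i(r) = \tfrac12 k (r - r_i^0)^2\);
the printed production bias of "1.0 kcal/mol·Å" is dimensionally readable
only as k = 1.0 kcal/mol/Å² in the ½ convention, and both the ½ and the
units are explicit flags so the alternative convention is one switch away.
The production window grid is centers 4.0–27.0 Å at 1 Å spacing
(24 windows). Exchanges alternate odd/even neighbor pairs with the
standard Metropolis bias-energy cross-difference; the window→replica
assignment is asserted to stay a bijection.

WHAM unbiasing iterates the standard self-consistent equations until the
window free-energy constants change by less than 10⁻⁶ kcal/mol (both the
0.5 Å default bin width and the tolerance are arguments). The audit path
is a 1-D Langevin particle on an analytic quartic double well run through
the *same* exchange machinery: the WHAM profile must match the known
potential within 0.15 kcal/mol over the well-sampled range. Two details
make the audit exact rather than approximately right. First, on that
steep double well a 0.25 Å bin is used: with 0.5 Å bins the within-bin
variation of the potential near the edges (|U′| of several kcal/mol/Å)
dominates the comparison. Second, the reference is the *bin-integrated*
Boltzmann free energy, \(-k_BT\ln\int_{bin} e^{-\beta U}dx\): WHAM
estimates bin probabilities, so comparing against the potential evaluated
at the bin center would charge WHAM with a discretization bias it does
not have.

## Observables

* **Q-score** — fraction of native contacts with r ≤ tol·r₀ (tol = 1.2),
  over any contact sublist; exactly 1 at the native pose.
* **Bending score** — \(S_i = \langle \hat u_{i-w,i}\cdot
  \hat u_{i,i+w}\rangle\) over sugar beads of one strand (optionally
  both). The span w = 10 bp (one helical repeat) is the unique small span
  for which an ideal straight helix scores exactly 1 — on a helix, vectors
  between sugars one full turn apart are parallel to the axis; any shorter
  span inherits an azimuthal component and scores below 1 even for
  straight DNA. w is a parameter.
* **Bound-core assignment** — Core *c* is bound when the Q-score of its
  own Core–RE sublist is ≥ 0.5 (threshold configurable), with an optional
  hysteresis band to suppress flicker at the threshold; transitions and
  first-passage steps are recorded.
* **Survival fits** — intermediate-state lifetimes are fitted with
  \(P e^{-t/\tau}\) by log-linear least squares on the (Kaplan–Meier,
  censoring-aware) survival curve, mirroring the straight-line-in-log
  presentation such kinetics are usually given; a censored-exponential
  MLE is available by flag. The fit residual (RMSE in log space) flags
  multi-exponential misfit.
* **PMF from histograms** — −k_BT ln p(r), min-anchored; empty bins are
  undefined (NA), not zero. No 4πr² Jacobian by default ("approximate
  free energy" convention); available by flag.
* **Connectivity types** — with the four Cores on quarter-sites 1–4
  (half-site 1 = quarters 1,2) and the TET a dimer of dimers, the
  partition of quarter-sites induced by TET partnership is one of three
  canonical pairings: {13|24} → type 1, {14|23} → type 2 (crossed),
  {12|34} → type 3 (partners sharing a half-site). The label is invariant
  under subunit relabelling, and frames with fewer than four bound Cores
  are skipped with a count (or are an error in strict mode).
* **Occupancy grids** — 3-D voxel histograms of a selection centroid,
  normalized to probabilities, written in DX text format for iso-surface
  viewing.

## The synthetic fixtures

`make_toy_fixture()` builds the systems the tests and the workflow run
on. They are deliberately small stand-ins that reproduce the *statistical
structure* the analyses assume, not p53 itself:

* `free_dna` — a straight duplex with a consensus RE (AAACATGTTT
  half-sites) starting 10 bp from one end, the production placement.
* `mini_core_dna` — a compact helical mini-domain (24 beads, Gō-folded)
  with a positively charged 8-bead tail, docked on half-site 1; the
  docked pose defines the Core–RE contact list.
* `tetramer_toy` — four Core–linker–TET subunits. The 10-bead Cores sit
  on the four quarter-sites on alternating DNA faces; the TET segments
  form a dimer of dimers (partners 1–2 and 3–4) above the duplex; linkers
  are strung at rest bond length along arcs routed away from the DNA;
  intra-linker pair terms, Core–Core contacts across the longitudinally
  adjacent pair, and per-Core Core–RE contact lists are generated from
  the reference pose. Construction ends with a short deterministic
  zero-temperature damped relaxation to relieve residual steric strain,
  so the returned pose is a true near-minimum.

With `start = "unbound"` the Cores are displaced 15 Å off the DNA (with
small seeded jitter) and the linkers re-strung; from there, thermal
dynamics rebinds the quarter-sites. Because binding is driven by
short-ranged Gō contacts plus strongly screened electrostatics, and the
search is diffusive, the demonstration asks a *qualitative* question —
does the bound-core count climb 1 → 2 → 3 → 4 without falling back —
mirroring the sequential recognition scheme, not any absolute rate.

What the fixtures do **not** emulate: real domain folds and contact maps,
sequence-specific DNA mechanics, the competition between sliding and 3-D
diffusion over ~100-bp tracks, and the absolute free-energy scale of
binding. Passing tests therefore validate the machinery (energies,
forces, sampling, unbiasing, bookkeeping), not biological numbers.

## Numerical choices

* Timestep 0.1 reduced ps (0.05 for the stiff 1-D audit and short-γ
  equilibrations); uniform bead mass 50 (dynamics at this resolution is
  diffusive, so relative masses are immaterial; config-overridable).
* Gō contacts clamp their energy below 0.5 r₀ and excluded volume below
  0.4 σ (force held at the clamp point) to keep early, badly overlapped
  configurations integrable instead of overflowing.
* Non-bonded pairs come from a Verlet list with a 4 Å skin, rebuilt when
  any bead has moved half a skin; electrostatics is truncated-shifted at
  50 Å.
* The energy decomposition is accumulated per category in a fixed order
  and must sum exactly to the total.
* Degenerate inputs error early: empty selections, empty contact lists,
  thresholds outside (0,1), non-monotone window centers, non-overlapping
  window histograms (the gap is reported), non-finite coordinates (the
  offending step is reported).

## Scale of the bundled computations

The simulations run by the tests, the workflow scripts and the acceptance
script are desk-scale by design: 24–274-bead systems, 10⁵–10⁷ steps,
minutes on one CPU. The study-scale quantities this class of model is
used for — absolute association rates of order 100/10/0.1 per
millisecond for successive Core bindings, ratios between CTD-neutralized
and unmodified search speeds, or kcal-scale barrier differences from
50-replica umbrella runs of the full 4×393-residue tetramer on 100-bp
DNA — require orders of magnitude more aggregate sampling (~100 ms mapped
time) and crystal-structure-derived contact maps, and are out of scope for
the bundled problem sizes; the workflow prints the same observables on the
toy systems instead.

## Known limitations

* The statistical local tables shipped are a generic worm-like propensity,
  not the sequence-dependent loop-library tables of the original
  disordered-region parameterization; users can supply their own tables.
* The linker per-pair strengths default to uniform; the published
  optimization against atomistic contact maps is not reproduced.
* A standard screened-Coulomb form cannot reproduce a "10% of the 1 Å
  energy at 25 Å" figure sometimes quoted for 210 mM — with λ_D ≈ 6.6 Å
  that point lies at ~1.7 Å — so the conventional Debye–Hückel form is
  implemented as such and the discrepancy is documented rather than
  reverse-engineered.
* Reduced-time durations are not mapped to physical time internally.
* No hydrodynamics, explicit ions, or constant-pH; His is always +1e.
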