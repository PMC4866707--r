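---
title: "Analysing fuzzy activation-domain / coactivator complexes"
author: "fuzzytraj"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing fuzzy activation-domain / coactivator complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuzzytraj)
library(dplyr)
```

## The problem this package addresses

Transcriptional activation domains (ADs) are intrinsically disordered
segments of gene-specific transcription factors. When an AD binds an
activator-binding domain (ABD) of a coactivator such as Mediator's
GAL11/MED15 subunit, it does not settle into one pose: the bound state is a
*fuzzy* ensemble in which a short amphipathic helix slides, rotates and
swaps which of its bulky hydrophobic anchor side chains (a tryptophan or a
phenylalanine, typically spaced i/i+4) occupies the coactivator's
hydrophobic surface pocket. Characterising such a complex from molecular
dynamics (MD) trajectories requires a small set of coupled observables
rather than a single structure:

* **pocket occupancy** — per-frame distances from the pocket floor to each
  candidate anchor, reduced to discrete switch-like states;
* **helix orientation** — the angle between the AD helix and a reference
  coactivator helix;
* **secondary structure over time** — per-residue, per-frame helix/coil
  assignment, helical occupancies and helix-boundary statistics;
* **per-residue interaction energetics** — which AD residues dominate the
  binding energy, and how contributions switch over time;
* **phase-space coverage** — whether an independent reference ensemble
  (e.g. NMR models) falls inside the conformational space the trajectory
  visits;
* **sequence-encoded helical propensity** — a helix-coil model linking AD
  sequence to measurable activity.

fuzzytraj implements this pipeline end to end for multi-model PDB and
CHARMM/NAMD DCD inputs, together with a synthetic-trajectory generator
that produces the same statistical structure with known ground truth, so
that every stage is testable without any external download.

## Geometric observables

`pocket_distance_series()` measures, per frame, the Euclidean distance
from the CA of the pocket-floor residue to the side-chain heavy-atom
centroid of a candidate anchor. The centroid reduction is robust to
aromatic ring flips; glycine falls back to CA. `helix_angle_series()`
takes the literal CA(i)→CA(j) vectors of stated endpoint residues for each
helix — not a fitted axis — and reports the unsigned angle in [0°, 180°].
A least-squares axis would be smoother but would decouple the observable
from the residue-level definition users state; the endpoint convention is
therefore the default and only mode.

`classify_occupancy()` reduces two distance traces to the four states
`A_IN`, `B_IN`, `BOTH`, `NONE` with a two-threshold hysteresis rule: an
anchor is counted *in* once its distance drops below `d_in` and stays in
until it exceeds `d_out`. Defaults are `d_in = 6.5` Å and `d_out = 8.5` Å.
Published distance traces of this system plot raw distances without a
stated cutoff; 6.5 Å comfortably contains the docked-state distance band
while 8.5 Å is beyond it, and the 2 Å hysteresis band suppresses label
chatter from thermal fluctuation at the threshold. Both are arguments, and
run boundaries (concatenated independent simulations) always reset the
latch so no state leaks across runs.

`superpose()` performs least-squares rigid-body superposition (via
bio3d's Kabsch implementation) and `rmsf_profile()` the per-residue CA
root-mean-square fluctuation about the mean structure. A selection of
fewer than three, or collinear, atoms is refused as degenerate.

## Secondary structure

`assign_ss_frame()` detects backbone hydrogen bonds with the
Kabsch–Sander electrostatic score

$$E = q_1 q_2 \left(\frac{1}{r_{ON}} + \frac{1}{r_{CH}} -
\frac{1}{r_{OH}} - \frac{1}{r_{CN}}\right) \cdot 332\ \mathrm{kcal/mol},
\qquad q_1 q_2 = 0.42 \times 0.20,$$

with a bond assigned when $E < -0.5$ kcal/mol. Two consecutive
i→i+4 turns yield α-helix (H), i→i+3 patterns 3₁₀ (G), β-bridge ladders E,
remaining n-turn interiors T, everything else coil (C) — the five-class
reduction used in AD timeline plots. Isolated β-bridges are folded into E
rather than given their own class. Amide hydrogens are used when present
and otherwise reconstructed at 1.01 Å along the bisector-opposed direction
of N given C(prev) and CA; the first residue of a chain and prolines
cannot donate. Residues with missing backbone atoms are labelled C with a
warning instead of failing, so a single damaged residue cannot abort a
timeline.

This is a deliberate design choice over reimplementing STRIDE (the tool
behind the original timelines): STRIDE's empirical propensity terms are
not published to reproducible precision, whereas the Kabsch–Sander rule is
fully specifiable and testable against constructed geometries — an ideal
poly-alanine helix at (φ, ψ) = (−57°, −47°) is labelled H throughout its
interior, a 3₁₀ helix at (−49°, −26°) G, and extended or polyproline-II
chains coil. Occupancy percentages from different assigners differ by a
few percent on borderline frames; conclusions should rest on the H
fraction trends, not on decimals.

`helical_occupancy()` defaults to α-only counting, with
`include_310 = TRUE` available because published occupancy figures are
ambiguous about 3₁₀ stretches; the pipeline's summary table reports both.
`helix_boundaries()` reports, per consensus block (contiguous residues at
or above `min_persistence` helical occupancy), the modal per-frame start
and end residues, with ties broken toward the N-terminus so the statistic
is deterministic.

## Per-residue interaction energetics

`pair_energy()` evaluates, for an intermolecular atom pair,
Lennard-Jones $4\varepsilon_{ij}[(\sigma_{ij}/r)^{12} -
(\sigma_{ij}/r)^6]$ with Lorentz–Berthelot combination and a screened
Coulomb term $k_e q_i q_j / (\varepsilon(r)\, r)$ with
$k_e = 332.0636$ kcal·Å/(mol·e²) and a distance-dependent dielectric
$\varepsilon(r) = 4r$ by default (vacuum mode exists for oracle tests).
`decomposition_matrix()` sums these over all atom pairs between each AD
residue and the coactivator within a 12 Å cutoff (no switching function;
`cutoff = Inf` reproduces the brute-force all-pairs sum exactly), and
`binding_series()` row-sums the decomposition into a total per frame —
additivity holds to float precision by construction.

This screened-Coulomb decomposition deliberately replaces a full
MM-GBSA treatment (no Generalized-Born solvation, no nonpolar surface
term, no bonded or entropic contributions). Absolute kcal/mol values are
therefore **not** comparable to solvated binding free energies and are
never asserted anywhere in the package; what the decomposition preserves —
and what the analyses consume — is the *rank order* of residue
contributions and their switching pattern over time. Because only
intermolecular pairs are evaluated, intramolecular 1–4 scaling never
arises. The bundled parameter table (`load_ff_params()`) is a minimal
synthetic template library — backbone N/H/CA/C/O, a CB pseudo-side-chain,
a second CG atom for the six bulky hydrophobics, acetyl/N-methylamide
caps — with per-residue charges that sum exactly to the formal charge.
It is not a transferable force field; users with real systems should
supply their own TSV.

## Phase space

`phase_points()` zips the angle trace and the two anchor-distance traces
into per-frame triples; `phase_density()` bins them on a regular grid
(default 10° × 1 Å × 1 Å, edges anchored at multiples of the bin width so
the grid does not move under subsetting). `populated_fraction()` asks, for
each reference point (e.g. each model of an NMR ensemble evaluated as a
one-frame trajectory through the *same* observable code), whether its bin
— or any neighbour in the 1-bin Chebyshev shell, on by default — holds at
least `min_frac` of all samples (default 0.001). "Highly populated" has no
canonical definition; the defaults were chosen for stability under ±1
bin-width perturbation, they are all arguments, and
`populated_fraction_sweep()` reports the sensitivity of the fraction to
the threshold, which should accompany any reported number. The fraction is
provably monotone non-increasing in `min_frac`, which the test suite
asserts.

## The helix-coil model

`helicity()` evaluates a Lifson–Roig single-sequence partition function
exactly, by a transfer matrix over (previous, current) residue-state
pairs with coil boundary conditions. A helical residue flanked by helical
neighbours carries its helix weight $w_{aa}$; helical residues at helix
ends carry the nucleation weight $v = 0.048$; coil residues weight 1.
The per-residue helicity reported is the probability of the *regular*
(w-state) helical conformation — the quantity that tracks measurable
helix content — and mean helicity is its sequence average in percent.
The transfer matrix is verified against exhaustive $2^n$ enumeration for
sequences up to length 10 in the test suite.

The bundled weight table is literature-informed and intentionally uses a
short-helix scale in which tryptophan is a strong helix former
($w_W = 1.55$, near leucine and above valine/serine/glutamate), because
short AD helices are the regime of interest and tryptophan substitutions
are precisely what converts weak AD variants into strong ones. Under this
table the three bundled variants order as their measured fold-activation
does: cAD-like96 (~12.6% mean helicity) ≫ cAD-like07 (~3.4%) > the
inactive parent motif (~2.3%). Temperature enters through a van 't Hoff
enthalpy term ($\Delta H = -0.9$ kcal/mol per residue); pH and ionic
strength are accepted and recorded for provenance but do not modify the
weights — a documented limitation relative to full empirical predictors
such as AGADIR, whose electrostatic and capping-motif machinery this
package does not attempt to reproduce. Terminal acetylation/amidation
flags multiply the nucleation weight of a helix reaching the blocked
terminus (factors 1.6 and 1.3); under the bundled table blocking termini
never decreases homopolymer helicity, which is asserted as a test for
this parameter set specifically.

`correlate_activity()` is ordinary least squares of fold-activation on
mean helicity with a t-based 95% prediction interval (n − 2 degrees of
freedom), exposed with broom-style `tidy()`/`glance()` methods and an
`autoplot()`. With the three bundled variants it is a demonstration
(r² on three points is not evidence); the regression machinery is
calibrated instead on synthetic panels — across 500 replicated
24-variant panels the generating slope falls inside its own 95% CI about
95% of the time.

## What the synthetic generator emulates — and what it does not

`synth_spec()` / `generate_trajectory()` produce a two-chain complex:

* a **rigid coactivator** built as an up-down-up-down four-helix bundle
  (the shape of activator-binding domains), ~80 residues, with a
  designated pocket-floor residue mid-helix;
* a **27-residue peptide** whose central cooperative helix block
  (default residues 10–21) forms and melts as a two-state Markov chain
  (stationary probability 0.9, mixing 0.3), with optional ±1-residue end
  breathing; helical stretches are built at ideal (−57°, −47°) dihedrals,
  coil stretches from the broad β/PPII basin (φ ∈ [−180°, −60°],
  ψ ∈ [60°, 180°]) so coil can never score as helix;
* a **switch-like occupancy chain** over `A_IN`/`B_IN`/`BOTH`/`NONE` with
  transition matrix $(1-m)I + m\,\mathbf{1}\pi^T$, which has stationary
  distribution exactly $\pi$ (default 0.5/0.3/0.1/0.1, $m = 0.2$); every
  run starts with the F-anchor docked, matching the deposited complex
  trajectories' layout of four concatenated 100-frame runs at 10 ns;
* a per-frame **orientation angle** drawn from a truncated normal
  (default 90° ± 35°) and realised exactly as the angle between the
  bundle's reference helix and the peptide helix axis — the realised
  angle is recorded as ground truth;
* isotropic Gaussian **coordinate noise** (default σ = 0.1 Å).

Docking is geometric: the pocket CA is placed `dock_distance` (5.5 Å)
from the docked anchor's side-chain centroid, approached radially off the
peptide cylinder with enough axial lean to keep the rejected anchor beyond
the 8.5 Å out-threshold; the coactivator tilts about the approach
direction and chooses its azimuth in closed form so its bulk stays behind
the pocket. The 5.5 Å default reflects that the CB/CG pseudo-side-chain
stands in for a full side chain whose centroid reaches several Å further
into a real pocket.

The generator is *geometric, not physical*: no sterics are resolved, no
forces are integrated and flailing coil tails can pass near (occasionally
through) the rigid bundle. Consequently (i) energetics on default
generated trajectories contain clash artefacts and are only meaningful on
the clean docked construction used in the tests; (ii) because the
synthetic pocket is a convex surface rather than a concavity, the residue
one turn C-terminal of a docked anchor can graze the bundle as closely as
the anchor itself — the rank-order check therefore uses the
tryptophan-anchor docked state, where it holds robustly. Passing tests on
generated data demonstrate that the *analyses* recover known ground
truth; they say nothing about force-field accuracy or the realism of any
particular MD protocol.

The noise default is measurement-scale jitter, not a model of dynamics:
thermal motion is correlated across bonded atoms, whereas independent
per-atom noise directly degrades hydrogen-bond geometry. Measured on an
ideal helix, the assigner's interior recall is 1.00 up to σ = 0.1 Å,
0.98 at 0.2 Å and 0.87 at 0.3 Å; σ is an argument for users who want to
study exactly that degradation.

## Numerical and interface choices

* Internal residue indexing is 0-based and contiguous across the system;
  deposited ("author") numbering is reachable only through
  `build_numbering_map()`, a checked bijection. This keeps the two
  numbering schemes that coexist in published material (author labels
  like "GCN4-W120" vs. merged continuous numbering in deposited files)
  from ever being confused silently.
* Frame spacing is configuration, never read from DCD headers
  (concatenated files carry unreliable timing); the deposited-set default
  is 10 ns per frame.
* DCD files are written in the CHARMM/NAMD 32-bit little-endian dialect;
  reading auto-detects endianness, validates the declared frame count
  against the file size, and reports truncation with the number of
  complete frames.
* PDB coordinates beyond ±9999.999 Å are a refusal (fixed columns), and
  multi-model files are validated for per-model atom-count consistency
  before parsing.
* Pipeline configuration is a plain R list or YAML file
  (`read_config()`); runs write TSV outputs plus a JSON manifest with the
  config hash, seed, package version and input checksums. Stage order and
  fail-fast selection resolution (all author-numbered selections resolved
  before any trajectory is read) are enforced by `run_stage()`.
* All stochastic code draws from one global RNG stream seeded once per
  run, so outputs are bit-reproducible given (config, seed).

Problem sizes in the shipped checks were chosen to keep the full suite in
the minutes range while leaving comfortable statistical margins: 400-frame
default trajectories (the deposited-set shape), 5000-step occupancy chains
for stationary recovery (errors judged at 3 standard errors with an
effective-sample-size correction for autocorrelation), 2000 frames for the
RMSF closed form, and 500 replicate panels for regression-slope coverage.

## Known limitations

* Quantities that would require external inputs are not reproduced and
  not asserted: absolute MM-GBSA binding energies (no solvation model
  here), the r² of the published 24-variant helicity-activity regression
  (those sequences live in an external supplement, and the original
  helicities came from a closed web service), and free-peptide helicity
  percentages from undeposited simulations. The machinery to compute all
  of them from user-supplied inputs is present and tested on synthetic
  data.
* The secondary-structure assigner is DSSP-style, not STRIDE; absolute
  occupancy percentages can differ by a few percent between assigners.
* The Lifson–Roig table is a bundled default, not a fitted parameter
  set; `lr_params(path = ...)` accepts replacements.
* The generator's pocket is convex and its coil is unphysical (see
  above); it validates analyses, not simulations.
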