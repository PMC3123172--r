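---
title: "Delimiting helical transmembrane domains by sliding-window stochastic peptide modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delimiting helical transmembrane domains by sliding-window stochastic peptide modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Single-spanning membrane receptors carry a helical transmembrane domain
(TMD) whose exact boundaries are hard to pin down: sequence-based
topology predictors disagree with each other by up to eight residues, and
modelling a whole candidate TMD at once produces length-dependent
artifactual polymorphism.  `tmdscan` attacks the problem locally: every
19-residue window of the target sequence is modelled independently as a
peptide in an apolar (membrane-like) medium, each window's best models
are scored with structural descriptors, and the per-residue aggregation
of those descriptors across all windows covering a residue locates the
domain center and limits.  The 19-residue window is the longest for
which the archived models of one window stay mutually consistent (about
1 Å all-atom RMSD), so each window contributes a stable local vote.

## The conformational search

Backbone conformations are drawn from a 64-state phi/psi alphabet.  Each
structure assigns one state per residue; all-atom coordinates follow
from ideal geometry (N-CA 1.458 Å, CA-C 1.525 Å, C-N 1.329 Å, omega
fixed at 180°, a single most-populated-in-helix rotamer per side chain,
polar amide hydrogens built explicitly).  The packaged alphabet was
derived once by k-means (k = 64, on the torus embedding of the angles)
from dihedrals harvested from a small nonredundant set of reference
chains; the table ships as a plain-text file and can be replaced via
`load_alphabet(path)`.

The search itself is an iterative Boltzmann-stochastic procedure
(`run_peplook()`): each step draws `structures_per_step` structures from
per-position state probabilities (initially uniform), ranks them by
energy, boosts the probability of (position, state) couples found only
among the most favorable structures, damps couples found only among the
least favorable, renormalizes with a floor (1e-4) for ergodicity, and
keeps a global archive of the 99 best-energy distinct structures.  The
prime model is the archive's best.  Probabilities stabilize after about
ten steps per residue, which is the default step count.

Two update parameters deserve comment because the method is sensitive to
them.  The favorable/unfavorable tiers are the top and bottom 1% of each
ranked step (not, say, deciles): with hundreds to thousands of
structures per step a wide tier contains nearly every state at every
position, so *tier-exclusive* couples — the only ones the update may
touch — become a residual noise set and the search never concentrates.
Narrow tiers make the update approximate a cross-entropy fit to the best
structures, which converges (the test suite checks optimality against
exhaustive enumeration on a small alphabet, and helicity of the scanned
models through the package-level recovery check).  The boost and damp
factors are ×2 and ×0.5; gentler factors converge too, only more
slowly.  Both are `sampler_config()` arguments.

Structures with a non-bonded heavy-atom pair closer than 1.5 Å are
redrawn once and otherwise carried with a prohibitive sentinel energy:
they pad the unfavorable tier but can never reach the archive.

### Sampling budgets

The `"desk"` preset uses 500 structures per step (about 10^5 structures
per 19-mer window, a million per scan of a 29-residue input), sized so a
complete scan runs in minutes per master seed on one desktop CPU core;
the probability update - not the raw sample count - does the work, so
window searches at this budget land in the same basin as much larger
ones.  The `"full"` preset restores 10^4 structures per step for
production use.

## The energy model

Four non-bonded terms, all pairwise over atoms except the last
(1-2/1-3 bonded pairs excluded, 1-4 and beyond at full weight):

* **Lennard-Jones 6-12**, $A/d^{12} - B/d^6$, with $A,B$ from per-type
  well depths and radii under Lorentz-Berthelot combination.
* **Coulomb** with a distance-dependent dielectric: a sigmoidal
  (smoothstep) rise from 1 at 0.2 nm of interatomic separation to 80 at
  1 nm.  The screening argument is the interatomic distance (the
  classical distance-dependent-dielectric reading); a membrane-depth
  dependent variant would couple electrostatics to the insertion
  geometry and is not what a peptide-in-medium search needs.
* **Atomic hydrophobicity**:
  $\delta_{ij}\sqrt{|E^{tr}_i E^{tr}_j|}\,\frac{f_{ij}+f_{ji}}{2}\,
  e^{-(d - r^0_i - r^0_j)/2r_{sol}}$, where $\delta_{ij} = -1$ for two
  hydrophobic or two hydrophilic atoms and $+1$ otherwise, $E^{tr}$ is
  the atom's transfer energy (its per-area value times its isolated
  accessible-sphere area $4\pi(r^0 + r_{sol})^2$), and $f_{ij}$ is the
  fraction of atom $i$'s solvent-augmented sphere occluded by atom
  $j$'s (analytic spherical-cap formula, clamped at hard contact).  The
  term vanishes smoothly once the augmented spheres separate (~6.5 Å).
* **Medium transfer**: in water, $+\sum_i E^{tr}_i S_i$ over exposed
  surface (exposing hydrophobic surface costs energy); in the apolar
  medium used by the scan the same term with opposite sign - exposing
  *polar* surface costs energy.  This reversed-sign term is what drives
  the backbone to satisfy its hydrogen bonds; without it the search has
  no reason to prefer a helix over any compact coil.  In the membrane
  environment the term is replaced by the implicit-bilayer potential
  below.

Atoms are classed into seven types (aliphatic C, sp2/aromatic C, neutral
N, neutral O, S, charged N/O, polar H) carrying radius, well depth,
transfer energy and hydrophobicity flag; partial charges are assigned
per residue/atom.  All values live in a versioned YAML file
(`inst/extdata/forcefield.yaml`) and are documented stand-ins assembled
from standard published parameters - the original laboratory tables are
not public.

Inside the compiled sampling engine the exposed surface is approximated
by a pairwise occlusion sum ($S_i \approx S^{iso}_i \max(0, 1 -
\sum_j f_{ij})$); reported energies (`total_energy()`) use the exact
Shrake-Rupley surface.  The engine also tabulates the short-range
hydrophobicity/occlusion kernel (512 bins uniform in $d^2$) and prunes
residue pairs by CA distance; these are resolution/bookkeeping choices
that do not alter the model.

## The implicit bilayer

The membrane is a DPPC slab described by a water-phase interface
function $C(z) = 1/(1 + e^{\alpha(z_0 - |z|)})$ with $z_0$ and $\alpha$
fitted so that $C = 10^{-3}$ at the core half-width (1.35 nm) and
$1 - 10^{-3}$ at the water bound (1.8 nm): $C$ is 0 throughout the acyl
core and 1 in water, symmetric about the bilayer center $z = 0$.

A rigid peptide placed in the bilayer feels

$$E_{pot,mem} = \underbrace{-\sum_i E^{tr}_i S_i (1 - C(z_i))}_{E_{pho,mem}}
  + \underbrace{a_{lip}\sum_i S_i (1 - C(z_i))}_{E_{lip}}$$

with $a_{lip} = 0.018$: burying hydrophobic surface in the core is
stabilizing, burying polar/charged surface and perturbing lipid packing
cost energy, and a fully aqueous peptide is the zero reference.  (The
transfer term is written relative to water; an absolute-in-water variant
with the same parameters would make water the global optimum for a
poly-leucine helix, which the insertion physics - and the package's
poly-Leu/poly-Lys control - reject.)

`insertion_scan()` slides the peptide centroid along the membrane normal
(0.1 Å steps over ±10 Å by default) and tries 10^4 uniform random rigid
orientations (or a deterministic tilt/spin grid), recording the lowest
$E_{pot,mem}$ per z and the global best position and tilt.  The scan
pipeline uses the deterministic 10°×30° grid per model: it is noise-free
and as cheap as a few dozen random trials.

## Descriptors

* **Accessible surface** (`shrake_rupley_asa()`): 162-point deterministic
  sphere sampling (twice-subdivided icosahedron), probe 1.4 Å.  Per
  residue, the hydrophobic/hydrophilic area ratio **ASAr** uses the
  seven-type hydrophobicity partition; a hydrophilic denominator under
  0.1 Å² caps the ratio at 99.9 to keep averages finite.
* **Secondary structure** (`pex_assign()`): a residue is helical when its
  phi/psi couple lies within an 80° circle (wrapped angular distance) of
  (-57°, -47°) *and* it takes part in a backbone H···O hydrogen bond
  (< 3 Å) with the residue four (alpha) or three (3-10) positions away.
  The donor is always the later residue's amide H and the acceptor the
  earlier residue's carbonyl O - the only geometry a helix can realize.
  Beta is a 90° circle around (-129°, 123°); terminal residues lacking a
  dihedral are coil.  (The canonical helix center is sometimes printed
  with positive signs; the beta center's signs identify that as a typo.)
* **Environment percentage** (`mfp_percentage()`): the sum of
  Lennard-Jones + hydrophobicity pair terms between a residue's atoms
  and all other residues' atoms within 10 Å, normalized to the
  calibrated per-type mean and expressed as a percentage (clipped to
  [0, 200]).  The packaged calibration uses glycine-host ideal helices
  (each type embedded every fifth position so guest side chains never
  touch; proline hosted in an extended chain because a rigid ideal
  helix is not a conformation proline can adopt).  This calibration is
  explicitly non-canonical - the reference set behind the published
  per-residue means is not available - so trends, not absolute
  percentages, are the contract; `calibrate_mfp()` accepts any
  user-supplied reference set.

## The scan and the calls

`tmd_scan()` slides the window (length 19, shift 1), models every window
(`run_peplook()`), and aggregates per residue, excluding the four
positions at each window extremity: helicity (% of covering models
labelled helical), mean ASAr (smoothed over 5 residues), mean insertion
depth (per window center, smoothed over 7 centers; 3 is available via
`insertion_smoothing_window` - both figures circulate for this
parameter and the Methods value is the default), and mean environment
percentage.  Away from the sequence ends every residue is covered by 11
windows × 99 models = 1089 structures.

The insertion column is the mean *unsigned* depth $|z|$ of a window's
models: the bilayer is symmetric, so the optimal placement of any
peptide is sign-degenerate and signed means cancel toward zero for every
window, carrying no signal.

**Center call** (`call_tmd_center()`): the residue with the highest
smoothed ASAr.  When the insertion minimum falls on an adjacent residue
the pair is reported as a two-residue center; a discordance beyond one
residue is flagged but ASAr keeps priority.  When several maxima lie
within 5% of the top - the usual situation on a uniformly hydrophobic
stretch, where ASAr saturates into a plateau - the call is flagged
`double_maximum` and the insertion criterion arbitrates: the candidate
closest to the *centroid* of the penetration-depth profile is taken.
The centroid rather than the argmin because each window's archive
converges to one idiosyncratic structure whose insertion optimum jumps
by several Å window-to-window, while the depth-weighted centroid
averages over all windows and is stable across master seeds.

**Limit call** (`call_tmd_limits()`): the maximal contiguous run around
the center with helicity ≥ 75%, truncated symmetrically toward the
center to a 26-residue cap (the span a ≤ 30°-tilted helix needs to cross
the core plus interfaces), clipped to the sequence and flagged when the
run is shorter than 15 residues.

**Multi-species consensus** (`multispecies_consensus()`): profiles of
homologous sequences are mapped onto a supplied alignment (gaps carry no
values), averaged column-wise without weights, and the calls re-run on
the consensus; a species whose own ASAr maximum sits more than one
column from the consensus maximum is flagged as the isolated
double-maximum case.  Alignments are consumed, never computed.

## What the synthetic fixture does and does not test

`generate_fixture("synthetic_tmd")` builds a 19-residue hydrophobic core
(L/I/V/F/A) flanked by five-residue juxta-membrane caps that are
mirror-symmetric in residue class (acidic outside, Lys/Arg on the
cytosolic side, an interfacial tryptophan on both sides).  The symmetry
matters: it makes the constructed core midpoint coincide with the
physical insertion center, which is the quantity the package-level
parameter-recovery test measures (called center within ±2 of the
midpoint across master seeds).  Real TMDs are not composition-symmetric,
their cores are not uniformly hydrophobic, and their flanks carry
signal the synthetic caps lack (conservation, prolines, interface
aromatic belts); passing on the fixture therefore demonstrates that the
machinery recovers a planted signal at the stated noise level, not that
field performance on receptor families is reproduced.  The headline
receptor results additionally need full-length database sequences and
paper-scale budgets, both outside the desk scale.

## Numerical choices and limitations

* Ideal rigid geometry: no bonded terms, no side-chain search.  The
  default rotamer is the most-populated choice that is also
  helix-compatible at rigid geometry (aromatic chi1 trans; everything
  else gauche-); proline's ring is closed only approximately.
* The engine's pairwise-occlusion surface overcounts burial for deeply
  enveloped atoms (the sum is clamped at full burial); exact surfaces
  are used everywhere results are reported.
* Energies are not transferable free energies; only ranks and
  differences within one run are meaningful.
* Determinism: every stochastic stage is seeded (master seed → per
  window seed → engine RNG), and `run_peplook()` results are
  bit-reproducible for a seed.  A persistent energy memo
  (`peplook_memo()`) may be shared across runs on the same sequence -
  state energies are seed-independent - without changing any result.
* The ASAr cap (99.9) saturates on fully buried hydrophilic groups;
  calls on uniformly hydrophobic stretches therefore lean on the
  insertion arbitration by construction.
* Windows are modelled independently; no information flows between
  windows except through aggregation.

## A worked example

```{r example}
library(tmdscan)

seqs <- generate_fixture("synthetic_tmd", 29, seed = 1)
scan <- tmd_scan(seqs, scan_config(master_seed = 1))
scan$call
tidy(scan)          # the residue profile as a tibble
glance(scan)        # one-row summary
autoplot(scan)      # profile with center/limits overlaid
```
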