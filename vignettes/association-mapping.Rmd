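---
title: "Mapping residue-level protein-polyelectrolyte association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping residue-level protein-polyelectrolyte association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppnetmap)
```

## The problem

When a positively charged globular protein such as lysozyme is mixed with an
anionic polyelectrolyte such as poly(acrylic acid), the two form complexes
held together mainly by electrostatics and hydrogen bonds. A simulation of
such a mixture — here, a system of 16 protein copies and 8 polymer chains of
40 monomers in a periodic box — produces trajectories from which one wants
to answer residue-level questions: *which* residues face the polymer, how
stable those contacts are over time, how they vary from one protein copy to
another, and how the complex's structure and kinetics respond to charge
state (a pH proxy) and temperature.

ppnetmap implements that analysis stack for orthorhombic periodic
trajectories: the residue-level **association rate** statistic at its core,
plus geometric hydrogen-bond accounting, alpha-carbon contact kinetics,
bridge detection, radial distribution functions, and copy-averaged
structural metrics. Every analysis is validated against a synthetic
trajectory generator whose output has known ground truth.

## The association-rate statistic

For protein copy $c$, residue $i$, analysis frame $j$ and polymer chain
$k$, let $d_{i,j,k}^{(c)}$ be the minimum-image distance between the
closest pair of (residue atom, chain atom). The chain-wise minimum

$$d_{i,j}^{(\min)} = \min_{k} \; d_{i,j,k}$$

isolates the closest polymer contact of that residue in that frame,
giving (copies × residues) values per frame — 16 × 129 = 2064 for the
reference composition. Averaging over the $m$ analysis frames (default
$m = 10$, drawn at even stride from the trailing window of the
trajectory),

$$\bar d_i^{(c)} = \frac{1}{m} \sum_{j=1}^{m} d_{i,j}^{(\min)},$$

a copy counts as *associated* at residue $i$ when
$\bar d_i^{(c)} \le 0.35\,\mathrm{nm}$ — the hydrogen-bond distance
criterion — and the association rate is the percentage of copies
associated there:

$$\mathrm{AR}(i) = \frac{100}{n_c} \sum_{c=1}^{n_c} I_i^{(c)}, \qquad
I_i^{(c)} = \mathbf{1}\!\left[\bar d_i^{(c)} \le 0.35\,\mathrm{nm}\right].$$

Two conventions deserve explicit statement. First, the indicator in the
source publication is printed with its inequality directions swapped
relative to its stated purpose ("how many of the residues are within a
chosen threshold distance"); ppnetmap follows the stated purpose —
indicator 1 *within* the threshold — which every downstream
interpretation requires. Second, the boundary case
$\bar d = 0.35\,\mathrm{nm}$ counts as associated ("within" read
inclusively); an exact convention is needed for exact tests. The mean
distance $\bar d_i$ carries a copy index here even though the defining
equation does not annotate one: the indicator it feeds is explicitly
copy-indexed, so the mean must be too.

The same machinery yields the variability decomposition: per-frame mean
± sd across copies (time stability of the contact network) and per-copy
mean ± sd across frames (environmental variability between protein
molecules). The two grand means coincide by exchanging summation order,
which the tests assert.

```{r}
spec <- synthetic_spec(n_proteins = 16, n_residues = 12,
                       n_chains = 2, chain_length = 40)
man <- plant_manifest(association = data.frame(
  copy = 1:12, residue = 5, chain = 1, distance = 0.3))
gen <- generate_planted(spec, man, n_frames = 5, seed = 1)
res <- association_analysis(gen$trajectory)
res$ar[res$ar > 0]     # residue 5 planted in 12 of 16 copies -> 75%
```

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `threshold` (association) | 0.35 | nm | hydrogen-bond distance criterion applied to $\bar d$ |
| `m`, `window_ps` | 10, full tail | frames, ps | analysis-frame selection (largest stride that fits the window, ending at the last frame) |
| `d_cut`, `angle_cut` (H-bonds) | 0.35, 30 | nm, degrees | donor–acceptor distance; hydrogen–donor–acceptor angle, vertex at the donor |
| `cutoff` (contacts) | 0.6 | nm | Cα-to-any-polymer-atom contact criterion |
| `cutoff` (bridges) | 0.35 | nm | any-atom chain–protein link criterion, consistent with the association threshold |
| `bin_width`, `r_max` (RDF) | 0.02, min(half-box, 4) | nm | histogram resolution and range |

Distance-based analyses use all atoms of a residue unless a restricted
selection is passed (heavy-atom-only analyses are a selection away);
"nearest chain" ties break toward the lowest chain index, which never
affects the value of $d^{(\min)}$, only reporting.

## Hydrogen bonds, contacts, bridges

A geometric hydrogen bond requires donor–acceptor distance ≤ 0.35 nm
**and** hydrogen–donor–acceptor angle (vertex at the donor, between the
D→H and D→A directions) ≤ 30°, both boundary-inclusive; intra-residue
pairs are excluded, and when several hydrogens of one donor reach the
same acceptor only the best-angle one is counted, so a physical bond is
never double-counted. Species-pair accounting divides protein-involving
counts by the number of protein molecules and polymer–polymer /
polymer–water counts by the number of chains. Whether protein–protein
counts should include bonds within a single copy is genuinely ambiguous
in per-molecule reporting; both modes are provided and the default is
inclusive, since per-molecule magnitudes (~10² per copy) are dominated by
intra-protein bonding. Time series carry a block-averaged standard error
(5 equal blocks by default).

A contact is an alpha-carbon within 0.6 nm of *any* polymer atom,
counted once per Cα however many polymer atoms are near; a
pair-counting mode is exposed because "number of contacts" in
mindist-style tools counts pairs, and the two conventions differ
exactly when one Cα faces several monomers. Contact series are
normalized by the **sum** of protein and polymer molecule counts (24
for the reference composition); the caption convention "divided by the
total number of molecules" could also be read as a product, so the
normalizer is an explicit argument. The plateau estimator takes the
final third of the series as reference level, bands it by one standard
deviation of that window, and reports the earliest start time from
which every running mean stays inside the band — requiring the start to
precede the reference window itself, so a series still rising at the
end reports "none" rather than a spurious late plateau.

A bridge is a chain simultaneously linked to ≥ 2 protein molecules,
with links either any-atom proximity (0.35 nm) or protein–polymer
hydrogen bonds; one record per chain per frame.

## Radial distribution functions

`rdf()` supports site–site mode (every atom against every atom — used
for ion–protein structure, whose sharp condensation peaks need site
resolution) and com–com mode (one mass-weighted center per molecule,
made whole across the boundary before averaging — used for
protein–polymer arrangement). Normalization is the conventional
$g(r) = \langle h(r) \rangle / (N_A \, \rho_B \, V_{\text{shell}})$
with $\rho_B$ recomputed per frame from the box volume, so
fluctuating-box ensembles are handled correctly; self-pairs are
excluded (and $\rho_B$ uses $N_B - 1$) when the two selections
coincide. The absolute peak height of any reported $g(r)$ depends on
this normalization convention, which is stated rather than assumed
silently. Two invariants pin the implementation: an ideal gas gives
$g \approx 1$ within sampling error, and
$N_A \sum_b g_b \rho_B V_b$ returns the average pair count exactly.

## Structural metrics

RMSD uses a proper (determinant +1) least-squares superposition computed
by singular value decomposition, unweighted over the fit atoms, applied
per protein copy to its own Cα set — each copy is its own rigid
reference frame, matching the per-copy reporting convention. The
reference structure defaults to the first analysis frame; the
publication this analysis style follows does not state its reference,
so the default is the self-contained choice and a crystal-structure
reference can be passed instead. RMSF removes global rigid motion by
per-frame superposition onto the first window frame, measures per-atom
fluctuation about the window-mean position, and averages backbone atoms
(names N, CA, C, O) per residue. Rg is mass-weighted over the unwrapped
molecule; a molecule still spanning more than half the box after
unwrapping is an error, not a silent wrap artifact. Cross-copy
aggregation averages each copy over the window first, then reports mean
± sd across copies.

Sanity laws used as tests: fitted RMSD is zero along pure rigid-motion
trajectories and never exceeds the pre-fit value; isotropic Gaussian
jitter of width $\sigma$ per coordinate gives pre-fit RMSD and RMSF
$\approx \sigma\sqrt{3}$; points on a shell of radius $R$ give
$R_g = R$ exactly, and a uniform ball gives $R\sqrt{3/5}$.

## The synthetic-data generator

The generator exists because the analyses need inputs with *known*
answers. Its defaults state the reference composition: 16 proteins ×
129 residues, 8 chains × 40 monomers, 50% charged monomers, monomer
spacing 0.27 nm, Bjerrum length 0.7 nm, ionic strength 0.15 M, and a
protein net charge used as a pH proxy (+8 near-neutral, 0, −4 strongly
alkaline).

**Planted-geometry mode** builds bead-per-residue proteins (Fibonacci
spheres) and bead-per-monomer rod chains in disjoint regions ≥ 3 nm
apart, then places each manifest entry analytically: a planted residue
sits at exactly its declared distance from a designated chain atom
(anchors two monomers apart so plants never interfere; neighbouring
monomers are provably farther than the anchor), and a planted
donor–hydrogen–acceptor triple realizes its declared distance and angle
exactly on an isolated grid site. The box is sized at twice the content
extent so that even a planted residue far from its sphere leaves every
molecule within half a box edge. Ground truth (AR per residue, valid
H-bond count, contacts per frame, bridge sets) is computed from the
manifest alone, never from the generated coordinates, so
generator and analyzer cannot share a bug and agree by accident.
Optional uniform jitter below the criterion margins (plants sit ≥ 10%
inside or outside each criterion) turns exact tests into
noise-robustness tests.

**Toy Langevin mode** is an overdamped Brownian emulation, not an
atomistic model: rigid charged protein spheres (translation only — no
rotational diffusion, acceptable because surface charges are
distributed and only contact statistics are read off), bead-spring
chains (harmonic bonds, stiffness 80 kT/nm², thermal bond-length sd
≈ 0.11 nm), monovalent counterions, screened Debye–Hückel
electrostatics with
$\kappa^2 = 8\pi \lambda_B N_A I$ (Debye length ≈ 0.79 nm at 0.15 M
with $\lambda_B = 0.7$ nm, matching the closed form to 10⁻⁶ relative),
and a soft quadratic excluded volume (σ = 0.35 nm, 50 kT/nm²). The
electrostatic force is capped below 0.25–0.3 nm so the soft core always
wins at contact — without the cap, ion–monomer pairs collapse, which is
the classic point-charge pathology of soft potentials. Integration uses
Euler–Maruyama with dt = 0.001 reduced units after a clamped
steepest-descent warmup that relaxes initial overlaps; the stability
check errors out when the *deterministic drift* in one step exceeds
half a monomer spacing (thermal noise is unbounded by nature and is not
part of the stiffness criterion). Temperature and pH enter only through
the noise scale and the protein net charge — an explicit emulation with
no claim of chemical realism.

What passing tests on these systems show — and what they do not: the
planted tests prove the *analyzers* are exact; the Langevin trend tests
prove the whole pipeline reproduces the qualitative physics
(association falls as protein charge drops toward the polymer's sign;
contact-count fluctuations grow with temperature). They do not show
that any particular real system's numbers would be reproduced: real
trajectories have internal protein dynamics, explicit solvent and
atomistic detail the toy deliberately lacks.

## Problem sizes and numerical choices

The validation suite runs trend checks on a scaled-down composition
(4 proteins × 20 surface beads, 3 chains × 10 monomers, 5 random seeds
per condition, 4000 steps per run) — chosen as the smallest system in
which the charge and temperature trends are cleanly resolved above seed
noise, and run sizes the package's own tests adopt throughout.
Degenerate inputs fail loudly everywhere: empty selections, out-of-range
frames, non-positive boxes, triclinic cells, infeasible plant manifests,
orphan hydrogens, series too short for block averaging or plateau
estimation. Ties in ranking (equal AR) break by ascending residue id so
reports are reproducible. All internal units are nm / ps / amu /
elementary charge; PDB and XYZ Angstroms are converted at the file
boundary.

## Known limitations

- Orthorhombic boxes only; triclinic input is an explicit error.
- The GRO/PDB readers recover molecule boundaries from residue-number
  resets (and TER/chain records in PDB); exotic numbering schemes need
  an explicit topology.
- The Langevin mode has no rotational diffusion of proteins, no
  explicit solvent, and capped short-range electrostatics; it supports
  trend tests, not quantitative kinetics.
- Hydrogen-bond donor assignment without a bond table uses a 0.12 nm
  attachment cutoff, which assumes reasonably resolved geometries.
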