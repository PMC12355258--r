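# ppnetmap

Residue-level association mapping for protein–polyelectrolyte complexes
from molecular simulation trajectories.

When a charged protein (e.g. lysozyme, 129 residues, present as many
copies) is mixed with an oppositely charged polyelectrolyte (e.g.
poly(acrylic acid) chains), the species form complexes driven by
electrostatics and hydrogen bonding. Given a trajectory of such a mixture
in an orthorhombic periodic box, ppnetmap answers the residue-level
questions: which residues face the polymer, how stable those contacts are
in time, how they differ between protein copies, and how structure and
kinetics respond to charge state and temperature.

## The core statistic

For protein copy *c*, residue *i*, frame *j* and chain *k*, let
*d<sub>i,j,k</sub>* be the minimum-image distance between the closest
(residue atom, chain atom) pair. The pipeline computes

- the chain-wise minimum *d<sub>i,j</sub>*<sup>(min)</sup> = min<sub>k</sub> *d<sub>i,j,k</sub>*
  (one value per copy × residue per frame),
- its time average *d̄<sub>i</sub>*<sup>(c)</sup> over *m* analysis frames
  (default *m* = 10, even stride over the trailing window),
- the indicator *I<sub>i</sub>*<sup>(c)</sup> = 1 iff
  *d̄<sub>i</sub>*<sup>(c)</sup> ≤ 0.35 nm (the hydrogen-bond distance
  criterion, boundary inclusive),
- the association rate AR(*i*) = 100 × Σ<sub>c</sub>
  *I<sub>i</sub>*<sup>(c)</sup> / *n<sub>c</sub>*, in percent.

Around it: geometric hydrogen-bond detection (donor–acceptor ≤ 0.35 nm
and hydrogen–donor–acceptor angle ≤ 30°) with species-pair accounting and
per-molecule normalization; Cα–polymer contact kinetics (0.6 nm) with a
plateau-time estimator; protein–polymer bridge detection; center-of-mass
and site–site radial distribution functions; per-copy RMSD/RMSF/Rg with
cross-copy mean ± sd; and a synthetic trajectory generator (planted
geometry with exact ground truth, plus a toy Langevin polyelectrolyte
model) used to validate all of the above.

Supported formats: GRO and PDB structures, multi-model PDB and XYZ
trajectories (DCD via the `bio3d` package when installed). Internal units
are nm / ps / amu / elementary charge.

## Worked example

A planted synthetic system in which residue 5 of 12 out of 16 protein
copies is pinned 0.3 nm from a polymer chain:

```r
library(ppnetmap)

spec <- synthetic_spec(n_proteins = 16, n_residues = 12,
                       n_chains = 2, chain_length = 40)
man <- plant_manifest(association = data.frame(
  copy = 1:12, residue = 5, chain = 1, distance = 0.3))
gen <- generate_planted(spec, man, n_frames = 5, seed = 1)

res <- association_analysis(gen$trajectory)
res
#> association_result: 12 residues, 16 copies, threshold 0.35 nm
#>   top residues (AR%): 5=75.0 1=0.0 2=0.0 3=0.0 4=0.0

top_residues(res$ar, k = 3)
#>   residue_id ar_percent
#> 1          5         75
#> 2          1          0
#> 3          2          0
```

AR = 75% is exactly 12/16: the planted fraction is recovered, and every
unplanted residue reports 0. Contact kinetics and bridges from the same
trajectory:

```r
contact_timeseries(gen$trajectory)
#> contact_series: 5 frames, mean 0.667 contacts/molecule, plateau at none
detect_bridges(gen$trajectory$frames[[1]], gen$trajectory$topology)
#>   chain n_proteins                   proteins link_type
#> 1    17         12 1,2,3,4,5,6,7,8,9,10,11,12  distance
```

(The 12 planted Cα contacts over 16 + 2 = 18 molecules give 0.667 per
molecule; the one chain touching all 12 planted copies is reported as a
single bridge record.)

The full pipeline — association rates, hydrogen bonds, contacts, bridges,
RDF and structure metrics, each as a CSV plus a JSON run manifest — runs
from one configuration:

```r
cfg <- run_config(
  input = list(topology = "system.gro", trajectory = "traj.pdb"),
  output = "out/")
run_pipeline(cfg)
```

A thin command-line wrapper is installed at
`inst/scripts/ppnetmap.R` (`analyze`, `simulate`, `compare` subcommands
over the same functions).

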