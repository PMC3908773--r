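# FCCfold

Evolutionary search for protein folding in the hydrophobic–polar (HP)
model on the 3D face-centered-cubic (FCC) lattice.

## The problem

In the HP model a protein is a string over {H, P}: hydrophobic residues
(H) attract, polar residues (P) are inert. A structure is a self-avoiding
walk of the chain on a lattice, and its free energy counts hydrophobic
contacts:

    E(c) = − #{ (i, j) : j ≥ i + 2,  s_i = s_j = H,  p_i and p_j lattice-adjacent }

Finding the minimum-energy walk is NP-hard even in this stripped-down
model. The FCC lattice — integer points with even coordinate sum, 12
neighbours per site, step vectors with two nonzero ±1 components — is the
lattice of choice for such models: densest packing, near-ideal bond
angles, and no parity obstruction to contacts.

`FCCfold` is for researchers studying lattice protein models and
metaheuristic conformational search. It implements an evolutionary
algorithm whose strength is three lattice-aware local-search operators:

* **Rotation-based one-point crossover** — the exchanged tail is re-emitted
  under each of the 17 proper lattice rotations (9 square-based about the
  x/y/z axes, 8 triangle–hexagon-based about the body diagonals), applied
  as pure permutations of the absolute direction labels 1–12, which
  rescues most otherwise-clashing children (up to 18 candidates per
  oriented pair).
* **Generalized pull move** — each pulled residue may relocate to any of
  the ≤ 4 free common neighbours of the relevant site pair rather than
  only the vacated site; accepted only on strict energy improvement.
* **K-site move** — exhaustive re-routing of K consecutive residues
  between their anchors (default K = 3), depth-first with an admissible
  step-count bound pruning the search; equal-energy replacements allowed
  (mutation role).

Selection is binary tournament; survival is elitist (μ+λ) truncation; a
run is exactly reproducible from its seed. An exhaustive enumeration
oracle provides exact optima for short chains, and the classical
benchmark collections (8 sequences of 20–64 residues, ten 48-residue
sequences, fifteen 90–200-residue sequences, and five HP transforms of
real PDB proteins) ship as fixtures.

## Worked example

```r
library(FCCfold)
res <- foldHP("HPHPPHHPHPPHPHHPPHPH",   # benchmark S1, 20 residues
              populationSize = 10, iterations = 30, seed = 11, restarts = 3)
res
#> FoldResult: 20-residue HP chain
#>   best HH contacts: 23 (energy -23)
#>   restarts: 3 (per-restart bests: 23, 23, 23; mean 23.00)
#>   seed: 11
labelString(bestConformation(res))
#> [1] "7,10,9,5,12,10,8,2,6,5,9,11,8,10,1,3,11,5,4"
```

23 HH contacts is the known optimum for this sequence; the label string
is the conformation's absolute direction encoding (step vectors 1–12),
decodable with `parseLabelString()` and exportable as coordinates
(`writeConformationTSV()`) or an xyz CA trace (`writeConformationXYZ()`)
for any molecular viewer. Exact ground truth for short chains:

```r
optimalContacts(enumerateOptimum("PHHPPHH"))   # exhaustive over all SAWs
#> [1] 4
```

A command-line interface wraps the same functions:

```sh
Rscript inst/scripts/hpfold.R fold --benchmark S1 --pop 10 --iters 30 --seed 11 --restarts 3
Rscript inst/scripts/hpfold.R energy --seq PHHPPPPHPHPH --labels 5,6,8,10,1,5,11,8,7,1,11
Rscript inst/scripts/hpfold.R rotations
```

## Package tour

| area | functions |
|---|---|
| lattice geometry | `directionVectors()`, `fccNeighbors()`, `areAdjacent()`, `commonNeighbors()`, `fccRotations()`, `rotateLabels()`, `rotationsTable()` |
| conformations | `Conformation()`, `encodeConformation()`, `isValidSAW()`, `hhContacts()`, `foldEnergy()`, `randomSAW()` |
| operators | `rotationCrossover()`, `generalizedPullMove()`, `kSiteMove()`, `stepLowerBound()` |
| evolution | `eaConfig()`, `initializePopulation()`, `tournamentSelect()`, `survivorSelection()`, `runEA()`, `foldHP()` |
| ground truth | `enumerateOptimum()` |
| I/O | `readHPSequences()`, `loadBenchmarks()`, `aaBenchmarks()`, `hpEncode()`, `labelString()`, `writeConformationTSV()`, `writeConformationXYZ()`, `writeFoldReport()`, `hpfoldCLI()` |

The methods vignette (`vignettes/fcc-hp-folding.Rmd`) documents the
model, the operators, every tunable parameter with its default and
rationale, the numerical design choices, and known limitations.
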