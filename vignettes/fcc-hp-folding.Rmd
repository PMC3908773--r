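---
title: "Evolutionary HP folding on the FCC lattice: model, operators, and design choices"
author: "FCCfold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolutionary HP folding on the FCC lattice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(FCCfold)
```

## The model

The hydrophobic–polar (HP) model reduces a protein to a string over
$\{H, P\}$: hydrophobic residues ($H$) drive folding by attracting each
other, polar residues ($P$) are inert. A conformation embeds the chain on
the face-centered-cubic (FCC) lattice, here the set of integer points
$(x, y, z)$ with $x + y + z$ even. Two sites are adjacent when every
coordinate differs by at most 1 and the absolute differences sum to 2;
each site therefore has 12 neighbours, reached by the step vectors with
two nonzero components of magnitude 1. The FCC lattice is attractive for
protein models because it achieves the highest sphere-packing density,
yields near-ideal bond angles (60°, 90°, 120°, 180° between consecutive
bonds), and avoids the even/odd parity artefact of the simple cubic
lattice, in which residues with the same parity can never touch.

A conformation of an $n$-residue chain is encoded *absolutely* as $n - 1$
direction labels in $1..12$, each naming one of the fixed step vectors
(label 1 = $(+1,+1,0)$, …); the first residue is anchored at the origin
and conformations are compared up to translation only. A conformation is
*valid* when it is a self-avoiding walk (SAW): all residue sites pairwise
distinct. Absolute encoding (rather than relative turns) is essential
here, because the crossover operator rotates subchains by permuting
labels, which only makes sense when labels name fixed lattice directions.

The energy of a valid conformation $c$ for sequence $s$ counts
hydrophobic topological contacts:

$$E(c) \;=\; -\!\!\sum_{j \ge i+2} \mathbf{1}\!\left[s_i = s_j = H
  \;\wedge\; \|p_i - p_j\| \text{ adjacent}\right],$$

i.e. each pair of $H$ residues that are non-consecutive in the chain but
adjacent on the lattice contributes $-1$. Minimizing $E$ maximizes the
HH-contact count; all user-facing output reports the positive contact
count. The H–H restriction is part of the contact definition even though
compact statements of the sum sometimes leave it implicit; one direction
label in the source table (label 6) is printed with the same vector as
label 5, and is resolved to $(+1, 0, -1)$ — the unique choice that keeps
the 12 vectors distinct and closed under negation and that reproduces the
published label-permutation examples.

## Lattice rotations

The proper rotations of the cube that map the 12 FCC directions onto
themselves form a 24-element group. Seventeen of them (all except the
identity and the six 180° edge-axis rotations) are used as search
operators, in two families:

* **square-based** — the three fourfold axes $x$, $y$, $z$ at 90°, 180°,
  270°. Geometrically each such rotation turns three parallel squares of
  neighbours synchronously. 9 rotations.
* **triangle–hexagon-based** — the four threefold body-diagonal axes at
  120° and 240°, turning two triangles and a hexagon of neighbours. 8
  rotations.

Because every rotation maps the direction set onto itself, rotating an
entire subchain reduces to applying the induced permutation of labels
elementwise — no coordinate arithmetic at all. The package constructs the
17 matrices in closed form (Rodrigues rotation about each axis, entries
exactly integer) and derives each permutation by lookup; the test suite
checks the set against an independent enumeration of all signed
permutation matrices with determinant $+1$. The identity is kept separate
(as the "no rotation" crossover variant) rather than counted among
the 17.

```{r rotations}
length(fccRotations())
rotateLabels(fccRotations()[["sq-z-90"]], c(1, 1, 6, 4))
```

## Search operators

**Rotation-based one-point crossover.** A cut point is drawn uniformly in
$1..n-2$; the child takes its head labels from parent A and its tail from
parent B. Plain one-point crossover on lattice chains usually produces a
clashing (non-self-avoiding) child; to rescue it, the tail is additionally
re-emitted under each of the 17 rotations, giving up to 18 candidates
(identity included — the unrotated child is explicitly part of the worked
example in the source material, so "at most 17" is read as counting the
rotated variants). Invalid candidates are discarded. Each call produces
one oriented family (head from A); the driver calls the operator twice per
pair with roles swapped, which matches classic two-child crossover while
keeping the per-orientation candidate accounting.

**Generalized pull move (GPM).** The classic pull move relocates a residue
and drags its successors along, each moving into the site its predecessor
vacated. The generalized form lets every pulled residue move to *any*
free common neighbour of (a) the new site of its already-moved neighbour
and (b) its own current site — on the FCC lattice an adjacent site pair
has exactly 4 common neighbours, so each propagation step has at most 4
candidates, among which the vacated site always appears (the classic move
is a special case). Initiation is deliberately unbiased: start residue,
pull orientation (toward head or tail) and every candidate site are drawn
uniformly; a chain-end start reduces to an end move. If a pulled residue
has no free candidate the attempt aborts and the conformation is left
untouched. An attempt is accepted only on *strict* improvement of the
contact count; GPM is the hill-climbing engine, so allowing sideways
drift here would mostly shuffle conformations without gaining energy.

**K-site move (mutation).** A segment of $K$ consecutive residues
(default $K = 3$) is torn out and every self-avoiding replacement path of
exactly $K$ free sites between the flanking anchors is enumerated
depth-first, directions tried in label order $1..12$. The number of FCC
walks grows roughly tenfold per step, so partial paths are pruned with an
admissible bound: a path of $m$ placed sites is abandoned when
$m + b(\text{current}, \text{far anchor}) > K + 1$, where
$b(p,q) = \max\!\big(\max(|dx|,|dy|,|dz|),\, \lceil (|dx|+|dy|+|dz|)/2
\rceil\big)$. A literal "path length plus Euclidean distance" bound
would be unit-inconsistent on this lattice (every step has Euclidean
length $\sqrt 2$); $b$ is a true step-count lower bound — each step
changes a coordinate by at most 1 and reduces the $L_1$ distance by at
most 2 — so no feasible path of at most $K + 1$ steps is ever pruned, and
the pruned search provably returns the same candidate as exhaustive
enumeration (property-tested). The best-contact candidate wins, ties
broken by first discovery in the deterministic DFS order; it replaces the
original when its contact count is **at least** the original's. Unlike
GPM, equal-energy replacement is allowed: this operator plays the
mutation role, and sideways moves inject diversity. A segment touching a
chain end has a single anchor and grows freely; $K = n$ would leave no
anchor at all and is treated as a degenerate no-op.

All three operators preserve chain length, sequence and self-avoidance of
whatever they return, and the two move operators return the input object
unchanged whenever they do not accept.

## The evolutionary driver

Each generation draws `populationSize / 2` parent pairs by binary
tournament (the fitter of two uniform draws with replacement; ties
uniform). With probability `crossoverRate` a pair undergoes crossover in
both orientations, contributing every valid child; otherwise the two
parents are cloned into the offspring pool. Every new offspring then
receives a sweep of GPM attempts and, with probability `mutationRate`,
one K-site move. Parents and offspring finally compete under elitist
$(\mu + \lambda)$ truncation — a stable sort by contacts, keep the top
$\mu$ — so the best-so-far trajectory is non-decreasing by construction.
After a fixed number of generations the best conformation in the
population is returned; independent restarts keep the overall best.

Defaults (all overridable through `eaConfig()`):

| parameter | default | rationale |
|---|---|---|
| `populationSize` | 10 | the published short-benchmark setting (40 for the 48-residue set) |
| `crossoverRate` | 0.85 | published setting |
| `mutationRate` | 0.4 | published setting |
| `iterations` | 30 | published setting for chains up to ~48 residues; 100–150 for longer ones |
| `K` | 3 | published setting; the path search is $O(11^{K})$ per move |
| `gpmAttempts` | $4n$ | see below |
| `restarts` | 1 (10 for benchmark reproduction) | published tables report bests over repeated runs without stating the count |

Two generational details are not specified in the source material and are
this package's own choices: the number of parent pairs per generation
(half the population, so $\lambda \approx \mu$ before rotation expansion
keeps the truncation pool bounded) and the GPM budget per offspring. For
the budget, one attempt per residue proved too small: most attempts abort
on blocked sites or are rejected by the strict-improvement rule, and at
the published population/iteration settings the search then reaches the
published best energies in only ~15–20% of restarts on the harder short
benchmarks. Four attempts per residue raises that to ~40% per restart
(so ten restarts practically always succeed) at proportionate cost; that
is the default. Operator order within a generation is crossover → GPM →
mutation. Duplicate individuals are allowed — no twin-removal, which
belongs to other methods.

All randomness — R-level draws and the compiled operators alike — flows
through R's RNG, so a run is exactly reproducible from `(sequence,
config, seed)`; restarts consume one continuous stream.

## Exhaustive enumeration oracle

`enumerateOptimum()` computes the exact optimum for short chains by
depth-first enumeration of all SAWs, counting contacts incrementally.
With symmetry reduction (default) the first step is fixed to label 1 and
the first non-collinear step is restricted to orbit representatives under
the twofold rotation about the first-step axis; the only walk fixed by
that rotation is the straight chain, so exact walk counts are recovered
as $12 + 24\,C$ with $C$ the reduced non-straight count — a 24-fold
saving that leaves the optimum untouched. The default cap is $n = 7$
(about $2 \times 10^6$ walks unreduced, well under a second reduced);
the cap can be raised explicitly for one-off checks. The oracle is the
ground truth in the test suite: move operators and whole searches are
checked never to exceed it, and the search is required to *attain* it on
at least 95% of random short sequences at desk-scale settings.

## What the tests do and do not show

Test problems are random HP strings and random self-avoiding walks
(uniformized depth-first growth with backtracking), plus the published
benchmark collections shipped in `inst/extdata`. Random HP strings with
i.i.d. H/P letters emulate the composition of the benchmarks but not the
clustered hydrophobic runs of real proteins; random DFS walks are not
uniform over all SAWs (branch choices weight compact shapes slightly).
Neither matters for the properties tested — operator invariants,
determinism, oracle agreement — but passing tests on these inputs says
nothing about biological accuracy of HP ground states for real chains;
the HP/FCC model itself is a deliberately coarse abstraction.

Problem sizes used by the shipped suite: operator fuzzing at
$n \in [5, 20]$ (thousands of applications), oracle agreement at
$n \le 7$ over 50 random sequences (population 10, 30 iterations, 3
restarts), and benchmark reproduction for the 12-residue 1CNL chain and
S1–S4 of data set I (population 10, rates 0.85/0.4, 30 iterations, up to
10 restarts). The longer published benchmarks (S5–S8, the 48-residue set,
and the 90–200-residue collections) run with the same code paths via
`runEA()`/`foldHP()` or the command-line tool but take minutes to hours
and are not part of the automated suite; the reproduction script in the
README shows how to run them.

## Known limitations

* The search is heuristic: reported energies are lower bounds on contact
  counts actually attained, with no optimality certificate (unlike
  constraint-programming approaches, which in turn struggle with richer
  energy functions).
* Only the 17 fourfold/threefold rotations are used for crossover, as in
  the source method; the six edge-axis 180° rotations and all improper
  symmetries (reflections) are deliberately excluded.
* Energies are pure HH-contact counts; pairwise 20-amino-acid potentials,
  disulfide constraints and secondary-structure information are outside
  the scope, though the operator layer is agnostic to the fitness
  function.
* The amino-acid → HP encoder uses a configurable hydrophobic set
  (default {C, F, I, L, M, V, W}); no single set reproduces every
  published HP transform of real proteins, so shipped transforms are
  stored verbatim and the encoder is validated on spot-checked positions.
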