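---
title: "Designing RNA-RNA switches by constrained multi-objective optimization"
author: "RNASwitchDesign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing RNA-RNA switches by constrained multi-objective optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RNASwitchDesign)
```

## The design problem

An RNA-RNA switch is a pair of RNA strands engineered so that hybridization
through intermolecular base pairs toggles a functional structure — for
example, a trigger RNA that opens a stem sequestering a ribosome binding
site. Designing such a switch means finding sequences $x_1 \in \Sigma^{n_1}$
and $x_2 \in \Sigma^{n_2}$ (over A, C, G, U) whose predicted secondary
structures match three *extended target structures*: one for each isolated
strand and one for the hybridized complex. Targets are per-position arrays:
a position may demand a specific partner, demand to be unpaired, or carry a
wildcard — `*` (anything), `+` (paired), `@` (intramolecularly paired) or
`^` (intermolecularly paired). Intermolecular and intramolecular pairs may
cross, so kissing-hairpin complexes (external pseudoknots) are expressible
targets.

This is a multi-objective problem. Three objectives are minimized jointly:

* $f_\mathrm{dist} = d_\mathrm{hyb} + d_\mathrm{iso,1} + d_\mathrm{iso,2}$,
  the number of positions whose predicted state is inconsistent with the
  corresponding target;
* $f_\mathrm{int} = E_\mathrm{seed} + E_\mathrm{hyb} -
  (E_\mathrm{iso,1} + E_\mathrm{iso,2})$, which simultaneously rewards a
  stable *interaction seed* (the nucleation helix of complex formation, a
  proxy for a low activation barrier) and a large free-energy gain upon
  hybridization;
* $f_E = E_\mathrm{hyb}$, the energy of the complex itself.

GC content enters as constraints $g_1 = c_\mathrm{GC}^{inf} - c_\mathrm{GC}
\le 0$ and $g_2 = c_\mathrm{GC} - c_\mathrm{GC}^{sup} \le 0$, with overall
violation $v = \max(g_1, 0) + \max(g_2, 0)$. Rather than weighting the
objectives, the optimizer approximates the Pareto front under
*constraint dominance*: a feasible solution dominates any infeasible one;
two feasible solutions are compared by ordinary Pareto dominance (with
strict improvement in at least one objective required); two infeasible
solutions are ordered by $v$, with ties mutually non-dominating.

A `"single"` preset designs against the hybridized target alone, with
objectives $d_\mathrm{hyb}$ and $E_\mathrm{hyb}$ only.

## The interaction seed

The seed is a short helix of continuous intermolecular base pairs, at most
$w$ base pairs long ($w = 6$ by default), located inside the *seed
candidates*: endpoints of intermolecular pairs of the predicted complex
that are loop nucleotides in both independently folded strands (a pair
whose either endpoint is structured in isolation is excluded with its
partner). Two procedures are provided and agree with brute-force
minimization over all candidate-interior duplex windows:

* **constrained prediction** (`findSeedConstrained`): every non-candidate
  position is pinned to its independently folded state, candidates are
  barred from intramolecular pairing, and the complex is re-predicted with
  a single accessible region of at most $w$ nt — the selected duplex is the
  seed;
* **sliding-window scan** (`findSeedScan`): windows of up to $w$ nt slide
  along continuous candidate runs on both strands; each window pair is
  folded as a duplex-only complex and the lowest-energy result is kept. A
  window never straddles a gap in the candidate set.

The seed's energy is the hybridization energy of the seed helix alone; an
empty candidate set yields an empty seed with $E_\mathrm{seed} = 0$, so
$f_\mathrm{int}$ degrades gracefully when no interaction is predicted.
De-optimizing the seeds of undesired homodimers is out of scope.

## The built-in structure predictor

Evaluation needs a predictor for single strands and for two-strand
complexes that can represent external pseudoknots. The package ships a
deterministic, dependency-free baseline and an adapter contract
(`externalPredictor`) for thermodynamic programs that follow the
"sequence in, dot-bracket + energy out" convention; energies are always
treated as backend-internal units and backends are never mixed within a
run.

The baseline scores a structure as

$$S = \sum_{(i,j)} w(x_i, x_j) \;+\; 2\,\#\{\text{stacked pairs}\},$$

with pair weights $w(\mathrm{GC}) = 3$, $w(\mathrm{AU}) = 2$,
$w(\mathrm{GU}) = 1$, a stacking credit of 2 for every pair that extends a
helix (the discrete analogue of helix-stacking free energy, the dominant
stabilizing term in real RNA), a minimum hairpin loop of 3 nt, and energy
$E = -S$. Single strands are folded exactly by dynamic programming over
(score, stacked-pair count), so among co-optimal structures the most
helix-like one is returned, with remaining ties broken deterministically
(unpaired-first, leftmost partner). For complexes, all contiguous
antiparallel intermolecular duplex windows are enumerated and up to
`maxRegions` best-scoring non-overlapping windows are selected greedily
(one region by default, mirroring a single accessible region; ties go to
the leftmost window on strand 1, then strand 2); the remaining positions of
each strand are then folded intramolecularly. Because a window may connect
two hairpin loops, kissing-hairpin topologies are reachable. Structure
constraints (enforce a pair, prohibit all/intramolecular/intermolecular
pairing) are honored by both stages; contradictory constraints are an
error, never a silent default.

The stacking credit deserves a note, because it was a genuinely open design
choice. Under a pure pair-weight score, random 30-nt sequences have many
co-optimal structures (we measured a median of roughly 5-20), and the
deterministic representative flips wholesale under one or two point
mutations — the genotype-to-phenotype map becomes chaotic, which both
misrepresents real RNA folding and cripples any sequence optimizer. With a
stacking credit of 2 the optimum is unique for most random 30-mers (median
co-optimum count 1, measured by exhaustive counting, independently of any
design run). We therefore adopted stacking as part of the model rather
than as a tie-break only. The exact-enumeration oracle used in the test
suite scores structures by the same two-term definition, so the dynamic
program is verified against brute force at small lengths.

The seed window cap $w$ applies where the seed procedures use it; the
complex prediction itself uses one accessible region of unrestricted
length.

## The genetic algorithm

`runDesign` implements an NSGA-II loop specialized to sequence design:

1. **Initialization.** `sampleCompatible` assigns nucleotides along the
   *dependency graph* whose edges are the explicit pairs of all targets:
   each connected component is sampled jointly (randomized propagation with
   backtracking for cycles), intersecting the pairable alphabet
   {AU, UA, GC, CG, GU, UG} with per-position IUPAC constraints. Every
   solution the run ever touches is compatible with the targets and
   satisfies the constraints — a hard invariant the test suite exercises
   over $10^4$ applications per operator.
2. **Evaluation.** Isolated strands are folded with intermolecular pairing
   prohibited, the complex is folded, the seed is predicted by the
   constrained procedure, and the objective vector is assembled.
3. **Selection.** Parents and children are pooled, non-dominated sorting
   under constraint dominance assigns fronts, and the best `popSize`
   survive; inside the front that overflows, larger NSGA-II crowding
   distance wins (boundary solutions count as infinitely crowded).
4. **Reproduction.** Each child comes from binary tournament selection
   (winner by front, then crowding) followed by one of four operators
   chosen uniformly at random: *point mutation* (each position selected
   with probability $p_M$; touched components are resampled jointly),
   *negative design* (an undesired predicted pair is reassigned to a
   non-pairable combination), *positive design* (a missing target pair is
   set to G/C, orientation random within the constraints), and *crossover*
   (5' part of one parent joined to the 3' part of another at a random cut,
   with any straddling component repaired by resampling). Operators that
   cannot apply (nothing undesired or missing, impossible reassignment)
   fall back to point mutation. After initialization and every
   reproduction, *prohibited-motif mutation* resamples components
   overlapping matches of IUPAC motifs (homopolymer tracts of four or more
   nucleotides by default); this is a soft constraint — an uneliminable
   motif is kept and logged.

Defaults follow the benchmark settings: population 100, 150 generations,
$p_M = 0.03$, GC bounds 45-55 %, $w = 6$, tournament size 2. The stopping
criterion is the fixed generation budget; `earlyStopDistance = 0` lets
harness runs stop as soon as a perfect design has been evaluated (the
best-distance statistic is unaffected, since it is the minimum over all
evaluated solutions). A single seeded RNG stream drives every stochastic
choice, so identical seed and configuration reproduce the archive
byte-for-byte.

## Synthetic design targets and what they show

`generateFixture` emulates a *predicted dataset*: it draws a random
sequence pair (with joint GC content inside the design bounds, so the
generating pair is itself feasible), folds the strands in isolation and as
a complex with the chosen backend, and returns the three predicted
structures as targets. By construction a perfect, feasible solution
exists, which makes fixtures well-posed instances for parameter-recovery
experiments: `benchmarkDesigns` runs five independently seeded designs per
target at a grid of population sizes and reports the per-target best
$f_\mathrm{dist}$ (whose mean decreases with population size) and the
number of perfect runs.

These fixtures exercise the full pipeline but are easier than natural
targets in specific ways: their structures are exactly representable by
the predictor that evaluates the designs (no model mismatch), they carry
no sequence conservation constraints, and 30-nt strands are short. Passing
the benchmark therefore demonstrates that the optimizer can invert its own
predictor at realistic sizes — it does not certify design success against
natural, experimentally determined target structures, where published
results with thermodynamic predictors also show hard cases: even at
moderate population sizes some targets are perfectly designed in every run
while others rarely or never are, and our measured per-fixture success
profile shows the same dichotomy. The vignette's own position is that the
per-fixture success *rate* is a property of the target's basin structure,
while the monotone improvement with population size is a robust property
of the algorithm.

Problem sizes used by the shipped analyses were chosen to keep a complete
run on one CPU comfortable: the test-suite benchmark uses twenty 30+30 nt
fixtures with five runs each at populations 20 and 50 and a 100-generation
budget; `scripts/acceptance.R` uses eight fixtures under the same
protocol.

## Target notation

Targets are written either in extended dot-bracket — four independent
bracket families `()`, `[]`, `{}`, `<>` matched by per-family stacks over
the concatenated strands (so crossing families encode pseudoknots), `&`
separating the strands, wildcards `* + @ ^` — or in the compact S+ shape
notation: `U`/`_` runs of loop nucleotides with optional lengths, `[n`
opening a duplex of $n$ pairs closed by the matching `]`, `x` a loop-length
wildcard resolved from the declared strand length (at most one per strand),
and letters splicing in named motifs defined by a mandatory structure line
and an optional IUPAC sequence line (`A = "[[[[[["` with `A = "aggagg"`
constrains six upstream-duplex positions to AGGAGG). A top-level `]` whose
upstream half lives inside a motif fragment is taken literally and matched
at the dot-bracket level. The parser rejects conflicting motif
redefinitions rather than guessing. `readTargets` reads the three target
files, resolves `x` against the complex's strand lengths, and merges the
per-file IUPAC constraints by intersection.

## Numerical and degenerate-case conventions

* Distances are integers; energies are exact integers in the baseline
  backend, so objective comparisons use exact equality — no tolerances.
* All tie-breaks (traceback, window selection, seed scan, tournament,
  truncation) are deterministic or drawn from the seeded RNG; there are no
  hidden entropy sources.
* An empty seed has energy 0; a target with no explicit pairs yields
  singleton dependency components; `maxRegions = 0` reduces the complex
  fold to independent strand folds.
* Unsatisfiable target/constraint combinations (e.g. an enforced pair
  between nucleotides forced non-pairable by IUPAC codes) are reported
  with the offending positions before the GA loop starts.

## Known limitations

The baseline energy model is a two-term integer score, not a
nearest-neighbor thermodynamic model; absolute energies are not
comparable across backends, and results obtained with different backends
should never be mixed. Internal pseudoknots within one strand are not
predicted (only external ones through duplex windows). The complex model
allows a single accessible region by default, so targets needing two
interaction sites (some natural kissing complexes) cannot be matched
exactly. Homodimer seed de-optimization and probability/ensemble-defect
objectives are out of scope.
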