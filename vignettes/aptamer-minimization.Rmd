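---
title: "Minimizing DNA aptamers: model, algorithms and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minimizing DNA aptamers: model, algorithms and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aptamin)
```

## The problem

SELEX-selected DNA aptamers are usually longer than the structural element
that recognizes their target. When that element is a multiloop (a junction
where three or more helices meet), a natural minimization strategy is:
trim the ends as far as possible while the *refolded* molecule still forms
the junction, then search sequence space for more stable sequences that
fold into the same minimized structure, and finally restore the original
loop sequences that carry the recognition chemistry. `aptamin` implements
that loop end to end for single-stranded DNA.

The critical discipline, observed at every stage, is that structure
preservation is always established by refolding the actual candidate
sequence — never by deleting positions from a drawn structure. A trimmed
sequence can fold into an entirely different shape even when the deleted
positions were all unpaired in the parent's structure.

## The energy model

Secondary structures are pseudoknot-free sets of Watson-Crick and G·T
pairs. A structure's free energy of formation is the sum of independent
loop-face terms (the nearest-neighbor model):

* **stacks**: tabulated pair-on-pair stacking energies;
* **hairpin loops**: a length term (tabulated to 30 unpaired bases,
  logarithmic extrapolation `+ lxc·ln(u/30)` beyond) plus a terminal
  mismatch term; loops of exactly 3 take a closing non-GC penalty instead
  of the mismatch;
* **bulges and interior loops**: length term, asymmetry (Ninio) term
  capped at its tabulated maximum, terminal mismatches on both closing
  pairs; 1×1, 2×1 and 2×2 interior loops use their dedicated lookup
  tables; single-base bulges keep the stacking term of the flanking pairs;
* **multiloops**: the affine model `a + b·k + c·u` with `a` the closing
  penalty, `b` per helix meeting the junction, `c` per unpaired junction
  base, plus per-helix terminal-mismatch ("dangle") terms;
* **exterior bases**: terminal-mismatch terms per external helix end.

All parameters come from the bundled DNA Mathews-2004 free-energy tables
at 37 °C, stored and summed as integers in hundredths of kcal/mol; the
conversion to kcal/mol happens only at the API boundary, so identical
inputs give bit-identical energies on every platform. Enthalpy tables are
not carried: the model is evaluated only at the tables' reference
temperature and no enthalpy/entropy rescaling is implemented.

Dangle handling follows the common default of reference implementations
("d2"): both-side terminal mismatches are applied to every helix end in
exterior and multi loops regardless of whether the neighboring bases are
themselves paired. Isolated (lonely) pairs are permitted. Interior loops
are capped at 30 unpaired bases in the search (they are never favorable
beyond that; evaluation of a given structure has no cap).

### Folding

`mfe_fold()` is a Zuker-style dynamic program with the standard four
arrays (paired, multiloop segment, single-branch multiloop segment,
exterior), O(n³) time with the interior-loop span capped at 30. The
traceback is deterministic: at equal energy it prefers the pairing branch,
then the smaller 5′ index. On a 64-nt aptamer a fold takes ~5 ms, which is
what makes grid truncation scans and thousand-fold design walks practical.

Correctness is established two ways in the test suite: (1) for short
sequences the DP minimum is compared against an *exhaustive enumeration*
of every valid structure scored by the independent loop-sum evaluator —
equality is exact, in integer arithmetic; (2) energies and structures are
cross-validated against an established reference folding engine running
with the very same parameter file, to the engine's printed precision.

### A note on the published energies

The study this package operationalizes prints formation energies of
−24.7 AU for its 64-nt minimal aptamer, −26.1 AU for its best design and
−14.1 AU for the parent. Folding the printed 64-nt sequence with the
named parameterization (DNA Mathews-2004, 37 °C, default dangles) yields
−17.9 kcal/mol — and the reference engine the study names produces the
identical structure and energy, at every standard dangle/temperature
setting we tried. The printed "AU" values therefore do not correspond to
any setting of the named tools that we could identify; this package
reports what the stated model actually computes. One structural
consequence: at this parameterization the printed minimal-aptamer
sequence folds without a multiloop (two hairpin domains with interior
loops and a bulge), so the bundled fixture is exercised with
motif-agnostic settings (`motif_spec(min_branches = 0)`), while all
junction-dependent machinery is tested on synthetic parents with known
ground truth.

## Truncation scan

`truncation_scan()` enumerates the full grid of (5′ trim, 3′ trim)
combinations up to configurable maxima (default: half the parent length
per side, at least 10 nt retained), refolds every candidate and tests the
result against the motif specification. A grid subsumes both readings of
a "sliding window" over the two ends and is cheap at aptamer scale
(~1600 folds for a 80-nt parent ≈ seconds). The landscape is exportable
as TSV for plotting energy-versus-trim profiles.

`select_minimal()` picks the candidate with maximal total trim among
motif-preserving rows; ties are broken by lower folding energy, then by
smaller 5′ trim. The criterion is an argument (`"min_energy"` selects the
most stable preserving candidate instead) because the original selection
rule is not stated quantitatively anywhere we could follow.

Motif specifications allow position drift by default — any multiloop that
satisfies the branching/fragment/segment conditions matches, wherever it
sits — with an optional `near` anchor to pin matches to the original
coordinates. For exact-recovery tests the fragment condition is the sharp
tool: requiring the designed core structure as a verbatim substructure
makes the preservation flag flip exactly when a trim crosses from padding
into the outer stem.

## Inverse design

`inverse_fold()` is a seeded adaptive walk. Initialization draws a
constraint-compatible sequence whose paired positions hold complementary
dimers, sampled with weights 4 : 1 : 0.25 for G-C : A-T : G-T pairs —
starting near the stable end of the design space, where replacing A-T
with G-C pairs is the recognized stabilizing move, roughly doubles the
success rate and yields design batches whose best members are more stable
than typical first-feasible solutions. Each step mutates one position
drawn from the mismatched loop faces (positions whose predicted partner
differs from the target); target-paired positions are mutated as
complementary dimers. Moves that do not increase the base-pair distance
to the target are accepted; plateaus can therefore be crossed. A run
succeeds at distance 0, and fails after `50·n` mutations (the overall
budget) or `8·n` consecutive non-improving steps (a stall cutoff that
stops hopeless runs early; restarts are supplied by the batch, not by
retrying a run).

`run_design_batch()` derives per-run seeds from the master seed with a
Lehmer-style integer mix, so batches are reproducible run-for-run and
byte-for-byte in their JSON export, and embarrassingly parallel in
principle. Successes are deduplicated by exact sequence identity, scored
by MFE, screened for canonical G-quadruplex motifs (flagged designs are
listed but excluded from the ranking) and ranked by MFE ascending with
lexicographic tie-breaks. The ensemble-defect ("Boltzmann") objective of
partition-function design tools is deliberately out of scope: the
selection criterion here is the MFE structure, the quantity the rest of
the pipeline reasons about.

On the bundled 64-nt target structure, about 60% of runs succeed within
budget and a 100-run batch finds designs several kcal/mol more stable
than the original sequence — reproducing, on the correctly parameterized
scale, the qualitative published pattern that the best design outperforms
the final aptamer.

## Loop restoration, junction variants, screening

`restore_loop_sequences()` writes parent loop bases back into designated
unpaired intervals of the target (edits into paired positions are
errors), refolds, and reports whether the structure — and optionally the
motif — survived. `junction_variants()` builds the junction composition
series (`AAAA`, `TTTT`, `ATAT` by default) for downstream 3D modeling,
which is itself outside this package's scope.

`g4_scan()` implements the canonical quadruplex rule — four or more
G-runs of length ≥ 3 chained by loops of 1–7 bases — reported 5′-most
greedily and maximally, so hits never overlap. The rule's parameters are
arguments because "avoid quadruplexes" is a hazard statement, not a
detector specification; an intentionally conservative default was chosen.
Pseudoknots need no scan: the folding model cannot produce them, and
`pseudoknot_free()` exists as an explicit certificate for imported
structures.

## The synthetic parent generator

`make_synthetic_aptamer()` builds test parents with a known three-way
junction: GC-saturated stems (drawn per seed from {G,C} without triple
repeats, so no G-quadruplex motif can arise), A/T-content loops, junction
runs and unpaired padding. The generator *verifies by refolding* that the
designed structure is the MFE structure and redraws stems deterministically
until it is; it records every coordinate it used (padding, stem, loop and
junction intervals) plus a ready-made motif specification whose fragment
is the designed core. That gives ground truth for: exact padding recovery
by the truncation scan, preservation-flag flips at stem boundaries, loop
restoration, and end-to-end pipeline determinism.

What the generator does **not** emulate: parents whose designed structure
competes with near-isoenergetic alternatives, kinetically trapped folds,
chemically modified bases, and junctions with more than three helices.
Tests passing on synthetic parents demonstrate the machinery is correct,
not that any particular laboratory aptamer will tolerate truncation.

## Numerical and interface choices

* Integer hundredths of kcal/mol throughout; `INF = 10^7` marks forbidden
  geometries; additions saturate rather than overflow.
* 1-based positions in every user-facing report and file; dot-bracket,
  Vienna text (with `(-17.90)`-style energy suffix), CT, FASTA, TSV and
  JSON writers follow the field's plain-text conventions.
* Hairpin loops shorter than 3 are rejected when structures enter as text
  and by the evaluator; programmatic pair tables may carry them so that
  structure arithmetic (distances, rendering) stays total.
* The parameter loader reads the section-tagged plain-text `.par` dialect;
  the bundled tables ship as concatenable text chunks and their md5
  checksum is recorded in every output so results are traceable to the
  exact tables used.
* Problem sizes used by the shipped tests and the acceptance script —
  exhaustive oracle up to 16 nt (hundreds of structures per sequence),
  100-run design batches on the 64-nt target, truncation grids a few
  steps beyond the known padding — were chosen to exercise every code
  path at desk scale; all of them are arguments, not limits.

## Known limitations

* No partition function: no base-pair probabilities, no ensemble defect,
  no suboptimal enumeration (outside the test oracle).
* DNA only, 37 °C only; no RNA tables, no temperature rescaling, no salt
  correction, no co-folding of two strands.
* The adaptive walk is a local searcher; for targets with long-range
  traps its success rate drops and more runs (or looser stall limits) are
  the remedy.
* G-quadruplex detection is sequence-level pattern matching, not a
  thermodynamic competition model.
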