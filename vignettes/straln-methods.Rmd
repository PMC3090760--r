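---
title: "straln: model, algorithm and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{straln: model, algorithm and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(straln)
```

## The problem

Members of an ncRNA family conserve secondary structure more strongly
than sequence: a base pair can survive a *compensatory* double mutation
(G–C becoming C–G) that a sequence-only scorer counts as two
mismatches. When only one member of a family is known — too few to
train a covariance model — the practical search strategy is to align
that one query (sequence plus structure) against every region of a
genome. Two further facts shape the method: homologs frequently share
only a local core, with large insertions or deletions in hairpins,
loops and stems; and the target's structure is unknown, so nothing is
predicted for it. `straln` therefore computes the optimal **local**
structural alignment of a structured query against an unstructured
target under an **affine** gap model, together with the global,
semi-global and prefix/suffix-global variants it is assembled from.

## Score model

An alignment of query substring `S[x..y]` (with the structure
restricted to it) and target substring `T[x'..y']` is scored as the sum
of `delta(S[i], S[j], T[a], T[b])` over query pairs whose two endpoints
are both aligned to target characters, plus `gamma(S[i], T[a])` over
every other column pairing a query character with a target character,
minus `k*h + l*s` for `k` maximal gap runs totalling `l` spaces.
`reference_score()` implements this definition directly from an
explicit alignment and is the package's ground truth; all aligner
outputs are checked against it.

**Broken pairs.** Substrings may cover only one endpoint of a pair, and
an endpoint may face a gap. The printed source for the score model does
not fix this case, so the package defines it: the surviving aligned
endpoint scores `gamma`, exactly as an unpaired character. This is the
only consistent reading of the substring semantics (the restriction
`M[x,y]` drops half-covered pairs but keeps their characters), and the
exhaustive oracle uses the same rule, so the choice is exercised by
every equivalence test.

**Default scheme.** The defaults are `gamma` = +1 match / −1 mismatch;
`delta(u1,u2,v1,v2) = gamma(u1,v1) + gamma(u2,v2) + 2` when `(v1,v2)`
is Watson–Crick or wobble complementary and `− 2` otherwise; `h = 5`,
`s = 0.1`. The `delta` bonus is what rewards conserved pairing and
compensatory mutations; the `± 2` split makes a conserved pair with two
compensatory substitutions (score 0) preferable to a broken pair with
two mismatches (−2 each way after the pairing bonus is lost). Every
component is overridable through `scoring_scheme()` or a JSON config,
and the randomized test suites run over three schemes including a dense
random `delta` table.

## Algorithm

### Interval decomposition

Tables are not filled for all `O(m²)` query intervals. `decompose()`
generates the needed set from `(1, m)`: an interval `(p, q)` is
**PAIRED** when `(p, q)` is itself a pair (depends on `(p+1, q−1)`),
**SPLIT** when `p` pairs with `q' < q` (depends on `(p, q')` and
`(q'+1, q)`), and **UNPAIRED** when `p` pairs with nothing inside
(depends on `(p+1, q)`). Intervals are deduplicated, giving at most
`2m + 1` nodes (property-tested over random structures up to
`m = 200`). A note on orientation: the source text's paired case points
at the *larger* interval `(p−1, q+1)`; dependencies must shrink for the
recursion to terminate, and the inner description of the paired
situation recurses on `S[p+1..q−1]`, so the package treats the printed
direction as a typo and uses the inner interval.

### Tables and boundary states

Per interval and target slice `(e, f)` the engine keeps tables resolved
by the *state of the boundary columns*: `M` (query char on target
char), `T` (query char on space), `Q` (space on target char), plus a
zero-column state for empty alignments:

* `A1`/`G[L][R]` — global alignment of `S[p..q]` vs all of `T[e..f]`,
  by first/last column state (the nine boundary cases, in the order
  both-aligned, left-aligned/right-query-gapped, ...);
* `A2`/`P[ls]` — prefix-global (a possibly empty prefix of
  `S[p..q−1]` vs all of `T[e..f]`) keyed by first-column state, with
  the empty-prefix closed form `−h − s(f−e+1)` (an all-gap column run)
  contained in the `Q` component and also exported separately;
* `A3`/`R[rs]` — suffix-global on `S[p+1..q]`, the mirror image;
* `A4` — semi-global on the inner interval `S[p+1..q−1]`;
* `A = max(A1, A2, A3, A4)` — the four-way maximum over the cases
  full / proper prefix / proper suffix / inner substring.

The final local score is `max(0, max over e ≤ f+1 of A(1, m, e, f))`;
semi-global is `A(1, m, 1, n)`; global is the best `A1(1, m, 1, n)`
case.

Boundary states exist for exactly one reason: affine gap bookkeeping.
Appending a space to an alignment costs `s` when the touching boundary
column is the same gap type (the run continues) and `h + s` otherwise.
The paired recurrence charges `delta` and recurses inward when both
endpoints align; when an endpoint faces a space, the inner alignment's
matching boundary state decides `s` vs `h + s`. At a SPLIT join the
engine maximizes over a target split point `k ∈ [e−1, f]` and over the
two inner boundary states; when the left part ends and the right part
begins with the same gap type, the two runs are one maximal run and the
doubly charged `h` is added back. Whether such a spanning gap should be
charged one `h` or two is not fixed by the source text; the package
charges one (it is a single maximal run in the realized alignment), and
the exhaustive oracle confirms that reading — with a double charge the
equivalence tests fail.

The recurrence bodies themselves (the lemma formulas) are not printed
in the available text. They were **derived** from the fully described
case semantics and are certified in two independent ways rather than
transcribed: (1) mode-level equivalence of `align_local`,
`align_global` and `align_semiglobal` with exhaustive enumeration over
hundreds of randomized instances (sequences, regular structures with
nested pairs and multiloops, three schemes); (2) a table-level audit
comparing every exported `A1`/`A2`/`A3`/`A4`/`A` cell, per boundary
case, against enumeration buckets. This is the package's central
engineering decision.

### Traceback

No backpointers are stored. `traceback()` re-derives the achieving
candidate at each cell using bitwise-identical arithmetic to the fill,
following a fixed tie-break (A1 before A2 before A3 before A4; lower
boundary-case index first; smaller split point `k` first), which makes
outputs deterministic and reproducible. Score-only runs
(`traceback = FALSE`, used by the scanner) free each interval's tables
as soon as no parent needs them, keeping peak memory at `O(n²)` per
live interval.

## Numerical choices

* Infeasible cells use a saturating finite sentinel (−10³⁰) rather than
  `−Inf`; anything below −10²⁵ is reported to R as `−Inf`.
* Cross-implementation equalities (engine vs oracle vs
  `reference_score`) are asserted at an absolute tolerance of 1e−9. The
  gap extension default `s = 0.1` is not a dyadic rational, so the
  engine's incremental accumulation (`−(h+s)`, then `−s` per space) and
  the closed form `k·h + l·s` can disagree in the last few bits;
  demanding bitwise equality across independently ordered summations
  would be wrong. Within one engine run, fill and traceback *are*
  bitwise consistent by construction.
* Empty intervals and empty target slices are materialized as explicit
  base cases (`p > q`, `e = f + 1`), so every recurrence reads uniform
  tables instead of special-casing.

## Synthetic data

`make_family_fixture()` emulates the family-scanning experiment the
method is evaluated with: a random regular structure and a compatible
consensus; members derived by point substitutions (default rate 0.1,
applied as compensatory double substitutions at paired positions so the
donor structure stays interpretable) and at most one short indel
(≤ 5 nt) at an unpaired position; members embedded without overlap in
an i.i.d. uniform background so the genome is ~10× the total member
length; scanning windows of max member length + 20. What a green test
on this world establishes: the aligner separates lightly diverged
structured homologs from uniform random background at the
zero-false-positive threshold, and its ranked scores dominate the
global aligner's (partial AUC at FPR ≤ 0.1). What it does **not**
establish: performance on real genomes (biased composition, repeats,
structured decoys), on deeply diverged families, or the published
per-family numbers, which depend on Rfam 9.1 data and unpublished
random placements and are explicitly out of scope.

Threshold evaluation (`evaluate_thresholds()`) is rank-based: the
zero-FP threshold is the best decoy score and a member scoring ≤ it is
a miss; FPR-level thresholds are the smallest observed score keeping
the false positive rate under the level; the ROC uses the strict
`score > t` rule consistent with the miss rule, and the partial AUC for
FPR ≤ 0.1 is trapezoidal with linear interpolation at the cap,
normalized to `[0, 1]`. A window is labelled a real hit when it overlaps
a truth interval by ≥ 50% of the member length — the attribution rule is
not fixed by the protocol's description, so it is a documented choice
here.

## Known limitations

* Pseudoknots are rejected, by design; base triples likewise (one
  partner per position).
* The target's structure is never predicted or scored — conserved
  target structure not paired in the query contributes nothing.
* `O(m n³)` time per window is real: scanning uses windows (length
  ~`l + 20`), not whole-genome `n`. The complexity-trend test asserts
  the scaling empirically (~linear in `m`, ~cubic in `n`).
* One gap-penalty class (`h + sL`) for both strands of the alignment;
  no per-gap-type penalties, banding or pruning.
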