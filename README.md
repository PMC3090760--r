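# straln — local structural alignment of RNA with affine gap penalties

`straln` finds the optimal **local** structural alignment between a
query RNA whose secondary structure is known and a target sequence whose
structure is unknown, under an affine gap model. It is built for the
standard comparative task in non-coding RNA (ncRNA) discovery: take one
known family member (sequence + pseudoknot-free structure), slide along
a genomic sequence, and score every region for sequence *and* structure
similarity — rewarding, in particular, compensatory double mutations
that preserve base pairing. Local alignment with gaps matters because
homologs often share only a conserved core and differ by sizeable
insertions in hairpins, loops or stems; global structural aligners and
gap-free local ones miss those families.

## The model

The query is `S[1..m]` with a regular (non-crossing) base-pair set `M`;
the target is `T[1..n]`. An alignment of substrings `S[x..y]`,
`T[x'..y']` is a pair of equal-length gapped strings. Its score is

```
  sum over pairs (i,j) in M[x,y] with both endpoints aligned:  delta(S[i], S[j], T[a], T[b])
+ sum over other columns pairing query and target characters:  gamma(S[i], T[a])
- (k*h + l*s)        # k gap runs, l total spaces: a gap of length L costs h + s*L
```

A base pair whose partner is excluded from `S[x..y]` or faces a gap is
*broken*: its surviving aligned endpoint scores `gamma` like an ordinary
character. Defaults: `gamma` = +1/−1 match/mismatch; `delta` =
`gamma(u1,v1) + gamma(u2,v2) ± 2` by target complementarity;
`h = 5`, `s = 0.1`.

The optimum is computed by dynamic programming in `O(m·n³)`: the
structure decomposes the query into `O(m)` intervals (paired / split /
unpaired cases), and per interval the engine fills boundary-case-resolved
global, prefix-global, suffix-global and semi-global tables over all
target slices `(e, f)`, so that affine gap runs are charged `h` exactly
once even across interval joins. `A(p,q,e,f) = max(A1, A2, A3, A4)` and
the local optimum is `max(0, max_{e<=f+1} A(1,m,e,f))`.

## Worked example

```r
library(straln)

q  <- "GGGCGCAAGCCUAAGCGCCC"       # query with a 6-bp stem
db <- "((((((....))..)))).."
t  <- paste0("AAUC", "GGGCACAAGCCUAAGGGCCC", "UUAG")  # homolog inside decoy

align_local(q, db, t)
#> rna_alignment  score = 16.8  (k = 1 gaps, l = 2 spaces)
#>   query  [1..18]  GGGCGCAAGCCUAA--GCGC
#>   target [5..24]  GGGCACAAGCCUAAGGGCCC
```

The aligner clips the two unpaired 3' query positions, bridges the
target's two-base insertion with one affine gap (cost `5 + 2·0.1`), and
scores the mutated stem positions as conserved *pairs* via `delta` —
`reference_score()` (the direct, DP-free scorer) reproduces 16.8
exactly.

A miniature family-scanning experiment (synthetic fixture: 6 mutated
members embedded in a random decoy genome, window = max member length
+ 20):

```r
fx  <- make_family_fixture(n_members = 6, member_length = 30,
                           genome_length_factor = 6, seed = 7)
w   <- window_length_rule(vapply(fx$members, length, integer(1)))  # 55
rec <- scan(fx$query, fx$structure, fx$genome, window_len = w, step = 3)
lab <- label_scan_hits(rec, fx$truth)
evaluate_thresholds(lab$real_scores, lab$false_scores)[c("zero_fp_threshold",
                                                         "misses_zero_fp", "pauc")]
#> $zero_fp_threshold   21     # highest-scoring decoy window
#> $misses_zero_fp      0      # every embedded member scores above it
#> $pauc                1      # normalized partial AUC for FPR <= 10%
```

Other entry points: `align_global()`, `align_semiglobal()`,
`align_semiglobal_tables()` + `traceback()` (cell-level table audit),
`decompose()` (the interval decomposition), `brute_force_local()` and
`gotoh_local()` (certification oracles), `mutate_member()` /
`make_fixture()` (synthetic data), and a CLI:

```sh
Rscript inst/cli/straln align-local --query q.fasta --structure q.db \
    --target genome.fasta --out hits.tsv
Rscript inst/cli/straln scan --query q.fasta --structure q.db \
    --target genome.fasta --pad 20 --step 1 --out scan.tsv
```

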