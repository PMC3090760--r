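# user-facing aligners wrapping the C++ dynamic programming engine

prep_inputs <- function(query, structure, target, scheme) {
  query <- as_rna(query, id = "query")
  target <- as_rna(target, id = "target")
  st <- as_structure(structure, m = nchar(query$residues))
  stopifnot(inherits(scheme, "scoring_scheme"))
  # C++ side expects 0-based residue codes
  list(q = rna_codes(query) - 1L, t = rna_codes(target) - 1L,
       pairs = st$pairs, query = query, target = target, st = st,
       gamma = unname(scheme$gamma), delta = as.numeric(scheme$delta),
       h = scheme$gap_open, s = scheme$gap_extend)
}

# turn traced columns into an rna_alignment; score is attached verbatim
alignment_from_cols <- function(res, inp) {
  qc <- res$qcols; tc <- res$tcols
  qs <- strsplit(inp$query$residues, "", fixed = TRUE)[[1]]
  ts <- strsplit(inp$target$residues, "", fixed = TRUE)[[1]]
  s_prime <- paste0(ifelse(qc > 0, qs[pmax(qc, 1)], "-"), collapse = "")
  t_prime <- paste0(ifelse(tc > 0, ts[pmax(tc, 1)], "-"), collapse = "")
  qr <- if (any(qc > 0)) range(qc[qc > 0]) else c(1L, 0L)
  tr <- if (any(tc > 0)) range(tc[tc > 0]) else c(1L, 0L)
  rna_alignment(s_prime, t_prime, qr, tr, score = res$score)
}

run_engine <- function(query, structure, target, scheme, mode,
                       traceback = TRUE) {
  inp <- prep_inputs(query, structure, target, scheme)
  res <- .cpp_align(inp$q, inp$pairs, inp$t, inp$gamma, inp$delta,
                    inp$h, inp$s, mode, traceback)
  if (!traceback) return(res$score)
  alignment_from_cols(res, inp)
}

#' Optimal local structural alignment
#'
#' Finds the best-scoring global alignment between *some* substring of
#' the query (with the structure restricted to it, broken pairs allowed)
#' and *some* substring of the target, under the affine gap model.  The
#' score is never negative: the empty-vs-empty alignment (score 0) is
#' always available.
#'
#' @param query query sequence ([rna_sequence] or string).
#' @param structure query secondary structure ([secondary_structure] or
#'   dot-bracket string) of matching length.
#' @param target target sequence (structure unknown).
#' @param scheme [scoring_scheme].
#' @param traceback return the full [rna_alignment] (default); with
#'   `FALSE` only the score is returned, using far less memory (the
#'   score-only mode frees interval tables as soon as possible and is
#'   what the genome scanner uses).
#' @return [rna_alignment], or a numeric score if `traceback = FALSE`.
#' @examples
#' align_local("ACGU", "....", "ACGU", default_scheme())$score  # 4
#' @seealso [align_global()], [align_semiglobal()], [brute_force_local()]
#' @export
align_local <- function(query, structure, target, scheme = default_scheme(),
                        traceback = TRUE) {
  run_engine(query, structure, target, scheme, "local", traceback)
}

#' Optimal global structural alignment
#'
#' Whole query against whole target.
#'
#' @inheritParams align_local
#' @return [rna_alignment], or a numeric score if `traceback = FALSE`.
#' @export
align_global <- function(query, structure, target, scheme = default_scheme(),
                         traceback = TRUE) {
  run_engine(query, structure, target, scheme, "global", traceback)
}

#' Optimal semi-global structural alignment
#'
#' Best substring of the query aligned globally against the *whole*
#' target.
#'
#' @inheritParams align_local
#' @return [rna_alignment], or a numeric score if `traceback = FALSE`.
#' @export
align_semiglobal <- function(query, structure, target,
                             scheme = default_scheme(), traceback = TRUE) {
  run_engine(query, structure, target, scheme, "semiglobal", traceback)
}

#' Fill and expose the semi-global DP tables
#'
#' Runs the engine and returns the top-interval tables over all target
#' slices `(e, f)` for auditing: `A1` (nine boundary cases, in the
#' standard order: both ends aligned; left aligned/right query-gapped;
#' left aligned/right target-gapped; ...), `A2` (prefix-global, split by
#' left-boundary case aligned / query-gapped / target-gapped, plus the
#' all-gap closed form `-h - s(f-e+1)` as fourth component), `A3`
#' (suffix-global, split by right-boundary case, plus closed form), `A4`
#' (semi-global on the inner interval) and `A` (their maximum).  Each
#' table is an `(n+1) x (n+1)` matrix with rows `e = 1..n+1` and columns
#' `f = 0..n`; `f = e - 1` is the empty target slice; cells with
#' `f < e - 1` are `NA`, infeasible cells are `-Inf`.
#'
#' @inheritParams align_local
#' @return list with elements `A1` (list of 9 matrices), `A2`, `A3`
#'   (lists of 4), `A4`, `A` (matrices), `m`, `n`, and the retained
#'   workspace handle used by [traceback()].
#' @export
align_semiglobal_tables <- function(query, structure, target,
                                    scheme = default_scheme()) {
  inp <- prep_inputs(query, structure, target, scheme)
  ws <- .cpp_workspace(inp$q, inp$pairs, inp$t, inp$gamma, inp$delta,
                       inp$h, inp$s)
  ws$inputs <- inp
  class(ws) <- "straln_workspace"
  ws
}

#' @export
print.straln_workspace <- function(x, ...) {
  cat(sprintf("straln_workspace: m = %d, n = %d (top-interval tables retained)\n",
              x$m, x$n))
  invisible(x)
}

#' Trace an explicit alignment out of a DP cell
#'
#' Reconstructs, from a workspace built by [align_semiglobal_tables()],
#' the alignment realizing a finite table cell.  The traceback re-derives
#' the achieving recurrence candidate at every step with the exact
#' arithmetic of the fill (candidates are examined in a fixed order:
#' lower boundary-case index first, smaller target split point first), so
#' it is deterministic and the reconstructed alignment's
#' [reference_score()] equals the cell value up to floating-point
#' round-off in the gap terms.
#'
#' @param workspace result of [align_semiglobal_tables()].
#' @param table one of `"A"`, `"A1"`, `"A2"`, `"A3"`, `"A4"`.
#' @param case boundary case index (1..9 for `A1`; 1..3 plus 4 = the
#'   all-gap closed form for `A2`/`A3`; ignored for `A`/`A4`).
#' @param e,f target slice, `1 <= e <= f + 1 <= n + 1`.
#' @return [rna_alignment].
#' @export
traceback <- function(workspace, table = "A", case = 1L, e = 1L, f = NULL) {
  stopifnot(inherits(workspace, "straln_workspace"))
  if (is.null(f)) f <- workspace$n
  res <- .cpp_trace(workspace$ptr, table, as.integer(case),
                    as.integer(e), as.integer(f))
  alignment_from_cols(res, workspace$inputs)
}

# timing entry used by the complexity-trend tests: score-only fill
fill_time <- function(query, structure, target, scheme = default_scheme()) {
  inp <- prep_inputs(query, structure, target, scheme)
  t0 <- proc.time()[["elapsed"]]
  invisible(.cpp_fill_time(inp$q, inp$pairs, inp$t, inp$gamma, inp$delta,
                           inp$h, inp$s))
  proc.time()[["elapsed"]] - t0
}
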