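# Brute-force oracles.  These are intentionally naive and share no code
# with the DP engine: they enumerate every substring pair and every
# legal gapped alignment and take the exact maximum.  They exist to
# certify the engine on small inputs and are exported for users who want
# the same certification on their own schemes.

#' Exhaustive brute-force local structural alignment
#'
#' Enumerates every pair of substrings of query and target (including
#' empty ones) and every legal gapped global alignment between them,
#' scores each directly from the score definition, and returns the exact
#' maximum.  Exponential: refuses inputs longer than `max_size`.
#'
#' @inheritParams align_local
#' @param mode `"local"`, `"global"` or `"semiglobal"`.
#' @param max_size hard size cap (default 8) on both sequence lengths.
#' @return list with `score` and `alignment` ([rna_alignment]).
#' @seealso [align_local()], [gotoh_local()]
#' @export
brute_force_local <- function(query, structure, target,
                              scheme = default_scheme(), mode = "local",
                              max_size = 8L) {
  inp <- prep_inputs(query, structure, target, scheme)
  if (length(inp$q) > max_size || length(inp$t) > max_size)
    stop("brute_force_local: input longer than max_size = ", max_size,
         call. = FALSE)
  mode <- match.arg(mode, c("local", "global", "semiglobal"))
  res <- .cpp_brute(inp$q, inp$pairs, inp$t, inp$gamma, inp$delta,
                    inp$h, inp$s, mode)
  list(score = res$score, alignment = alignment_from_cols(res, inp))
}

# component tables by enumeration, for auditing the engine's workspace
brute_force_tables <- function(query, structure, target,
                               scheme = default_scheme(), max_size = 5L) {
  inp <- prep_inputs(query, structure, target, scheme)
  if (length(inp$q) > max_size || length(inp$t) > max_size)
    stop("brute_force_tables: input longer than max_size", call. = FALSE)
  if (length(inp$q) < 1) stop("brute_force_tables needs a nonempty query")
  .cpp_brute_tables(inp$q, inp$pairs, inp$t, inp$gamma, inp$delta,
                    inp$h, inp$s)
}

#' Textbook affine-gap local alignment score (Smith-Waterman-Gotoh)
#'
#' Sequence-only three-matrix local alignment with gap cost `h + s*L`,
#' implemented independently of the structural engine.  With an empty
#' query structure the structural local aligner must reproduce these
#' scores exactly; this function is the oracle for that reduction.
#'
#' @param query,target sequences ([rna_sequence] or strings).
#' @param scheme [scoring_scheme]; only `gamma`, `gap_open` and
#'   `gap_extend` are used.
#' @return numeric local alignment score (>= 0).
#' @export
gotoh_local <- function(query, target, scheme = default_scheme()) {
  qs <- rna_codes(query)
  ts <- rna_codes(target)
  m <- length(qs); n <- length(ts)
  if (m == 0 || n == 0) return(0)
  g <- unname(scheme$gamma)
  open <- scheme$gap_open + scheme$gap_extend
  ext <- scheme$gap_extend
  NEG <- -Inf
  # H: column ends in a match; X: gap in target string (query char vs
  # '-'); Y: gap in query string
  H <- matrix(NEG, m + 1, n + 1)
  X <- matrix(NEG, m + 1, n + 1)
  Y <- matrix(NEG, m + 1, n + 1)
  best <- 0
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      H[i, j] <- g[qs[i - 1], ts[j - 1]] +
        max(0, H[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      X[i, j] <- max(H[i - 1, j] - open, X[i - 1, j] - ext,
                     Y[i - 1, j] - open, -open)
      Y[i, j] <- max(H[i, j - 1] - open, Y[i, j - 1] - ext,
                     X[i, j - 1] - open, -open)
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  # alignments ending in a gap are also legal, but with h, s >= 0 they
  # never beat the best match-ending cell (or 0)
  best
}

# Second, independent pure-R enumerator for tiny instances: recursively
# builds all gapped alignments of fixed substrings as strings and scores
# them with reference_score().  Used to cross-check the C++ enumerator.
enumerate_alignments_r <- function(query, structure, target, scheme,
                                   max_size = 4L) {
  query <- as_rna(query); target <- as_rna(target)
  st <- as_structure(structure, m = nchar(query$residues))
  m <- nchar(query$residues); n <- nchar(target$residues)
  if (m > max_size || n > max_size)
    stop("enumerate_alignments_r: too large", call. = FALSE)
  qs <- strsplit(query$residues, "", fixed = TRUE)[[1]]
  ts <- strsplit(target$residues, "", fixed = TRUE)[[1]]
  best <- 0; best_aln <- empty_alignment()
  subranges <- function(len) {
    out <- list(c(1L, 0L))
    for (a in seq_len(len)) for (b in a:len) out[[length(out) + 1L]] <- c(a, b)
    out
  }
  for (qr in subranges(m)) for (tr in subranges(n)) {
    recurse <- function(i, j, sp, tp) {
      if (i > qr[2] && j > tr[2]) {
        aln <- rna_alignment(paste0(sp, collapse = ""),
                             paste0(tp, collapse = ""), qr, tr)
        sc <- reference_score(aln, st, scheme)
        if (sc > best) { best <<- sc; best_aln <<- aln }
        return(invisible(NULL))
      }
      if (i <= qr[2] && j <= tr[2])
        recurse(i + 1L, j + 1L, c(sp, qs[i]), c(tp, ts[j]))
      if (i <= qr[2]) recurse(i + 1L, j, c(sp, qs[i]), c(tp, "-"))
      if (j <= tr[2]) recurse(i, j + 1L, c(sp, "-"), c(tp, ts[j]))
      invisible(NULL)
    }
    recurse(qr[1], tr[1], character(0), character(0))
  }
  best_aln$score <- best
  list(score = best, alignment = best_aln)
}
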