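#' Gapped structural alignment between query and target substrings
#'
#' An alignment is a pair of equal-length strings over `{A,C,G,U,-}`.  A
#' column never holds `-` in both strings.  `query_range` / `target_range`
#' give the 1-based inclusive coordinates of the aligned substrings; an
#' empty substring is encoded as `start > end` (e.g. `c(1, 0)`).
#'
#' @param s_prime,t_prime gapped query and target strings.
#' @param query_range,target_range integer length-2 vectors.
#' @param score alignment score (filled in by the aligners; may be NA for
#'   hand-built alignments, use [reference_score()] to compute it).
#' @return object of class `rna_alignment` with fields `s_prime`,
#'   `t_prime`, `query_range`, `target_range`, `score`, `gap_count` (k:
#'   number of maximal gap runs across both strings), `gap_total` (l:
#'   total spaces) and `eta` (for each column of `s_prime` the query
#'   position it carries, NA at gap columns).
#' @export
rna_alignment <- function(s_prime, t_prime, query_range, target_range,
                          score = NA_real_) {
  stopifnot(is.character(s_prime), is.character(t_prime),
            nchar(s_prime) == nchar(t_prime))
  sc <- strsplit(s_prime, "", fixed = TRUE)[[1]]
  tc <- strsplit(t_prime, "", fixed = TRUE)[[1]]
  if (any(sc == "-" & tc == "-"))
    stop("column with '-' in both strings", call. = FALSE)
  if (any(!sc %in% c(RNA_ALPHABET, "-")) || any(!tc %in% c(RNA_ALPHABET, "-")))
    stop("alignment strings must be over {A,C,G,U,-}", call. = FALSE)
  query_range <- as.integer(query_range)
  target_range <- as.integer(target_range)
  eta <- rep(NA_integer_, length(sc))
  if (length(sc)) {
    qcols <- sc != "-"
    eta[qcols] <- query_range[1] + seq_len(sum(qcols)) - 1L
  }
  structure(list(s_prime = s_prime, t_prime = t_prime,
                 query_range = query_range, target_range = target_range,
                 score = score,
                 gap_count = count_gap_runs(sc) + count_gap_runs(tc),
                 gap_total = sum(sc == "-") + sum(tc == "-"),
                 eta = eta),
            class = "rna_alignment")
}

count_gap_runs <- function(ch) {
  if (!length(ch)) return(0L)
  g <- ch == "-"
  sum(g & !c(FALSE, g[-length(g)]))
}

#' @export
print.rna_alignment <- function(x, ...) {
  cat(sprintf("rna_alignment  score = %g  (k = %d gaps, l = %d spaces)\n",
              x$score, x$gap_count, x$gap_total))
  cat(sprintf("  query  [%d..%d]  %s\n", x$query_range[1], x$query_range[2], x$s_prime))
  cat(sprintf("  target [%d..%d]  %s\n", x$target_range[1], x$target_range[2], x$t_prime))
  invisible(x)
}

#' Reference scorer: the definition of the alignment score
#'
#' Computes the score of an explicit alignment directly from the score
#' model, independently of any dynamic programming: every query base
#' pair (restricted to the aligned query substring) whose two endpoints
#' are both aligned to target characters contributes
#' `delta(S[i], S[j], T[a], T[b])`; every other column pairing a query
#' character with a target character contributes `gamma`; a broken pair
#' (an endpoint facing a gap, or a partner outside the aligned
#' substring) has its surviving aligned endpoint scored with `gamma`;
#' and each of the `k` maximal gap runs of total length `l` costs
#' `h + s * (run length)`, i.e. `k*h + l*s` in total.
#'
#' This function is the package's ground truth: every score reported by
#' the aligners equals the reference score of the alignment they return
#' (up to floating-point round-off in the gap terms).
#'
#' @param alignment [rna_alignment].
#' @param structure [secondary_structure] of the *full* query; it is
#'   restricted to `alignment$query_range` internally.
#' @param scheme [scoring_scheme].
#' @return numeric score.
#' @export
reference_score <- function(alignment, structure, scheme) {
  stopifnot(inherits(alignment, "rna_alignment"),
            inherits(scheme, "scoring_scheme"))
  sc <- strsplit(alignment$s_prime, "", fixed = TRUE)[[1]]
  tc <- strsplit(alignment$t_prime, "", fixed = TRUE)[[1]]
  x <- alignment$query_range[1]; y <- alignment$query_range[2]
  st <- as_structure(structure)
  # pairs fully inside [x, y], in original query coordinates
  p <- st$pairs
  p <- p[p[, 1] >= x & p[, 2] <= y, , drop = FALSE]
  # column index of each query position
  col_of <- rep(NA_integer_, max(y, 0))
  qcols <- which(sc != "-")
  if (length(qcols)) col_of[alignment$eta[qcols]] <- qcols
  score <- 0
  paired_cols <- logical(length(sc))
  if (nrow(p)) {
    for (r in seq_len(nrow(p))) {
      ci <- col_of[p[r, 1]]; cj <- col_of[p[r, 2]]
      if (tc[ci] != "-" && tc[cj] != "-") {
        score <- score + scheme$delta[sc[ci], sc[cj], tc[ci], tc[cj]]
        paired_cols[c(ci, cj)] <- TRUE
      }
      # else: surviving endpoints fall through to gamma below
    }
  }
  match_cols <- which(sc != "-" & tc != "-" & !paired_cols)
  for (ci in match_cols) score <- score + scheme$gamma[sc[ci], tc[ci]]
  score - alignment$gap_count * scheme$gap_open -
    alignment$gap_total * scheme$gap_extend
}

#' @export
as.character.rna_alignment <- function(x, ...) c(x$s_prime, x$t_prime)

# empty alignment (score 0 by convention)
empty_alignment <- function() {
  rna_alignment("", "", c(1L, 0L), c(1L, 0L), score = 0)
}
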