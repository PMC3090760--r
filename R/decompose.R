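#' Structure-guided interval decomposition of the query
#'
#' The dynamic programming engine does not fill tables for all O(m^2)
#' query intervals: the set of needed intervals is generated from
#' `(1, m)` by repeatedly applying the dependency function zeta, driven
#' by the structure.  For an interval `(p, q)` (with the structure
#' restricted to it) exactly one case applies:
#'
#' * `PAIRED` - `(p, q)` is itself a base pair; the entries depend on
#'   the inner interval `(p + 1, q - 1)`.
#' * `SPLIT`  - `p` pairs with some `q' < q`; entries depend on
#'   `(p, q')` and `(q' + 1, q)`.
#' * `UNPAIRED` - `p` pairs with nothing in `[p, q]`; entries depend on
#'   `(p + 1, q)`.
#' * `EMPTY`  - `p > q`; dynamic programming base case.
#'
#' Intervals reachable through several split branches are deduplicated,
#' so the node count is at most `2m + 1`.
#'
#' @param structure [secondary_structure] (or dot-bracket string).
#' @param m query length; defaults to the structure's length.
#' @return data.frame with one row per interval in dependency order
#'   (children before parents): columns `p`, `q`, `case`
#'   (`EMPTY`/`PAIRED`/`SPLIT`/`UNPAIRED`), `split_at` (q' for SPLIT,
#'   NA otherwise), `child1_p`, `child1_q`, `child2_p`, `child2_q`.
#' @examples
#' decompose(parse_dot_bracket("((..))"))
#' @export
decompose <- function(structure, m = NULL) {
  st <- as_structure(structure)
  if (is.null(m)) m <- st$seq_length
  m <- as.integer(m)
  if (st$seq_length != m)
    stop("structure length does not match m", call. = FALSE)
  partner <- integer(m)
  if (nrow(st$pairs)) {
    partner[st$pairs[, 1]] <- st$pairs[, 2]
    partner[st$pairs[, 2]] <- st$pairs[, 1]
  }
  seen <- new.env(parent = emptyenv())
  rows <- list()
  emit <- function(p, q) {
    key <- paste0(p, ":", q)
    if (!is.null(seen[[key]])) return(invisible(NULL))
    seen[[key]] <- TRUE
    if (p > q) {
      rows[[length(rows) + 1L]] <<- data.frame(
        p = p, q = q, case = "EMPTY", split_at = NA_integer_,
        child1_p = NA_integer_, child1_q = NA_integer_,
        child2_p = NA_integer_, child2_q = NA_integer_)
      return(invisible(NULL))
    }
    j <- if (p >= 1 && p <= m) partner[p] else 0L
    if (j > q) j <- 0L  # partner outside the interval: p counts as unpaired
    if (j < p) j <- 0L
    if (j == q) {                       # PAIRED
      emit(p + 1L, q - 1L)
      rows[[length(rows) + 1L]] <<- data.frame(
        p = p, q = q, case = "PAIRED", split_at = NA_integer_,
        child1_p = p + 1L, child1_q = q - 1L,
        child2_p = NA_integer_, child2_q = NA_integer_)
    } else if (j > p) {                 # SPLIT at q' = j
      emit(p, j)
      emit(j + 1L, q)
      rows[[length(rows) + 1L]] <<- data.frame(
        p = p, q = q, case = "SPLIT", split_at = j,
        child1_p = p, child1_q = j, child2_p = j + 1L, child2_q = q)
    } else {                            # UNPAIRED
      emit(p + 1L, q)
      rows[[length(rows) + 1L]] <<- data.frame(
        p = p, q = q, case = "UNPAIRED", split_at = NA_integer_,
        child1_p = p + 1L, child1_q = q,
        child2_p = NA_integer_, child2_q = NA_integer_)
    }
    invisible(NULL)
  }
  if (m == 0L) emit(1L, 0L) else emit(1L, m)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
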