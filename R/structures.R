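#' RNA secondary structure as a set of base pairs
#'
#' A secondary structure over positions `1..seq_length` is a set of pairs
#' `(i, j)` with `i < j`, no position occurring in two pairs, and no two
#' pairs crossing (`i < k < j < l` is forbidden).  Crossing pairs
#' (pseudoknots) or shared positions are a hard error: the alignment
#' algorithm is only defined for regular (nested) structures.
#'
#' @param pairs two-column integer matrix (or data.frame) of base-pair
#'   positions; a `0 x 2` matrix or `NULL` encodes the empty structure.
#' @param seq_length length of the underlying sequence.
#' @return An object of class `secondary_structure`: list with `pairs`
#'   (ordered two-column matrix with i < j) and `seq_length`.
#' @examples
#' secondary_structure(rbind(c(1, 7), c(2, 6)), 7)
#' @export
secondary_structure <- function(pairs, seq_length) {
  seq_length <- as.integer(seq_length)
  stopifnot(length(seq_length) == 1L, seq_length >= 0L)
  if (is.null(pairs) || NROW(pairs) == 0) {
    pairs <- matrix(integer(0), ncol = 2)
  } else {
    pairs <- as.matrix(pairs)
    storage.mode(pairs) <- "integer"
    if (ncol(pairs) != 2) stop("pairs must have two columns", call. = FALSE)
    # order each pair as (i, j) with i < j, then sort by i
    flip <- pairs[, 1] > pairs[, 2]
    pairs[flip, ] <- pairs[flip, 2:1]
    pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  }
  colnames(pairs) <- c("i", "j")
  st <- structure(list(pairs = pairs, seq_length = seq_length),
                  class = "secondary_structure")
  check_regular(st)
  st
}

# hard errors for shared positions, out-of-range endpoints and crossings
check_regular <- function(st) {
  p <- st$pairs
  if (nrow(p) == 0) return(invisible(st))
  if (any(p[, 1] >= p[, 2]))
    stop("base pair with i >= j", call. = FALSE)
  if (any(p < 1L) || any(p > st$seq_length))
    stop("base pair position outside 1..", st$seq_length, call. = FALSE)
  pos <- c(p[, 1], p[, 2])
  if (anyDuplicated(pos))
    stop("two base pairs share position ", pos[duplicated(pos)][1], call. = FALSE)
  if (nrow(p) > 1) {
    # p sorted by i: pair a crosses a later pair b iff i_a < i_b < j_a < j_b
    for (a in seq_len(nrow(p) - 1)) {
      b <- (a + 1):nrow(p)
      inside <- p[b, 1] < p[a, 2]
      if (any(inside & p[b, 2] > p[a, 2]))
        stop(sprintf("crossing base pairs (pseudoknot): (%d,%d)",
                     p[a, 1], p[a, 2]), call. = FALSE)
    }
  }
  invisible(st)
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat(sprintf("secondary_structure: %d pairs over %d positions\n",
              nrow(x$pairs), x$seq_length))
  if (x$seq_length <= 120) cat(" ", write_dot_bracket(x), "\n")
  invisible(x)
}

#' Restrict a structure to a subsequence
#'
#' Implements the restriction `M[x, y]`: only pairs with both endpoints in
#' `[x, y]` are kept; a pair with one endpoint inside is dropped and that
#' endpoint becomes an unpaired character.  Coordinates in the result are
#' shifted to `1..(y - x + 1)`.
#'
#' @param st [secondary_structure].
#' @param x,y 1-based inclusive bounds; `x > y` gives the empty structure.
#' @return [secondary_structure] over the subsequence.
#' @export
restrict_structure <- function(st, x, y) {
  stopifnot(inherits(st, "secondary_structure"))
  if (x > y) return(secondary_structure(NULL, 0L))
  p <- st$pairs
  keep <- p[, 1] >= x & p[, 2] <= y
  secondary_structure(p[keep, , drop = FALSE] - x + 1L, y - x + 1L)
}

#' Parse a dot-bracket string
#'
#' Matched round brackets give the pair set; only `.`, `(` and `)` are
#' accepted (other bracket types would denote pseudoknots, which are out
#' of scope).  Dot-bracket cannot encode crossings, so the result is
#' always regular.
#'
#' @param db dot-bracket string.
#' @return [secondary_structure].
#' @examples
#' parse_dot_bracket("((...))")
#' @export
parse_dot_bracket <- function(db) {
  stopifnot(is.character(db), length(db) == 1L)
  ch <- strsplit(db, "", fixed = TRUE)[[1]]
  bad <- which(!ch %in% c(".", "(", ")"))
  if (length(bad))
    stop(sprintf("illegal structure character '%s' at position %d",
                 ch[bad[1]], bad[1]), call. = FALSE)
  open <- integer(0)
  pairs <- matrix(integer(0), ncol = 2)
  for (k in seq_along(ch)) {
    if (ch[k] == "(") {
      open <- c(open, k)
    } else if (ch[k] == ")") {
      if (!length(open))
        stop("unmatched ')' at position ", k, call. = FALSE)
      pairs <- rbind(pairs, c(open[length(open)], k))
      open <- open[-length(open)]
    }
  }
  if (length(open))
    stop("unmatched '(' at position ", open[1], call. = FALSE)
  secondary_structure(pairs, length(ch))
}

#' Write a structure as dot-bracket
#'
#' Inverse of [parse_dot_bracket()] (regularity guarantees round
#' bracket notation suffices).
#'
#' @param st [secondary_structure].
#' @return dot-bracket string of length `seq_length`.
#' @export
write_dot_bracket <- function(st) {
  stopifnot(inherits(st, "secondary_structure"))
  ch <- rep(".", st$seq_length)
  ch[st$pairs[, 1]] <- "("
  ch[st$pairs[, 2]] <- ")"
  paste0(ch, collapse = "")
}

#' Read a secondary structure from a file
#'
#' Two dialects are accepted: (a) a sidecar file whose first non-comment,
#' non-header line is a dot-bracket string; (b) a two-line FASTA-like file
#' (`>id`, sequence line, structure line) where the structure is taken
#' from the line after the sequence.  Lines starting with `#` are
#' comments.
#'
#' @param path file path.
#' @return [secondary_structure].
#' @export
read_structure_file <- function(path) {
  if (!file.exists(path)) stop("structure file not found: ", path, call. = FALSE)
  ln <- readLines(path, warn = FALSE)
  ln <- trimws(ln)
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  if (!length(ln)) stop("no structure line in ", path, call. = FALSE)
  db <- if (startsWith(ln[1], ">")) {
    if (length(ln) < 3) stop("FASTA-like structure file needs sequence and structure lines", call. = FALSE)
    ln[3]
  } else {
    ln[grepl("[().]", ln)][1]
  }
  parse_dot_bracket(db)
}

#' Check base-pair complementarity of a structure against its sequence
#'
#' Watson-Crick and wobble pairs
#' (`AU, UA, CG, GC, GU, UG`) are accepted.  Non-complementary pairs are
#' reported as warnings (the aligner itself does not require
#' complementarity of the query structure); with `strict = TRUE` they
#' raise an error.  Crossing pairs or shared positions are always a hard
#' error via the structure constructor.
#'
#' @param st [secondary_structure].
#' @param seq [rna_sequence] of matching length.
#' @param strict raise an error on non-complementary pairs.
#' @return character vector of warning messages (empty when all pairs are
#'   complementary), invisibly `character(0)` on success.
#' @export
validate_structure <- function(st, seq, strict = FALSE) {
  seq <- as_rna(seq)
  stopifnot(inherits(st, "secondary_structure"))
  if (st$seq_length != nchar(seq$residues))
    stop("structure length ", st$seq_length, " does not match sequence length ",
         nchar(seq$residues), call. = FALSE)
  ok <- c("AU", "UA", "CG", "GC", "GU", "UG")
  p <- st$pairs
  msgs <- character(0)
  if (nrow(p)) {
    ch <- strsplit(seq$residues, "", fixed = TRUE)[[1]]
    duo <- paste0(ch[p[, 1]], ch[p[, 2]])
    bad <- which(!duo %in% ok)
    msgs <- sprintf("pair (%d,%d) is non-complementary: %s-%s",
                    p[bad, 1], p[bad, 2], ch[p[bad, 1]], ch[p[bad, 2]])
  }
  if (strict && length(msgs)) stop(paste(msgs, collapse = "; "), call. = FALSE)
  msgs
}

# coerce dot-bracket string / secondary_structure
as_structure <- function(x, m = NULL) {
  st <- if (inherits(x, "secondary_structure")) x else parse_dot_bracket(x)
  if (!is.null(m) && st$seq_length != m)
    stop("structure length ", st$seq_length, " does not match sequence length ",
         m, call. = FALSE)
  st
}
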