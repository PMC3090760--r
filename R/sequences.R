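#' RNA sequence with identifier
#'
#' Constructs a validated RNA sequence.  Input is normalized the way the
#' aligner expects it: letters are upper-cased and DNA thymine is mapped to
#' uracil.  Any character outside `{A, C, G, U, T}` (either case) is
#' rejected; IUPAC ambiguity codes are deliberately not supported because
#' the scoring model is strictly four-letter.
#'
#' @param residues single string (or character vector of single letters)
#'   over the RNA/DNA alphabet; may be empty.
#' @param id text identifier.
#' @return An object of class `rna_sequence`: a list with elements `id`
#'   and `residues` (single uppercase RNA string).  All coordinates used
#'   with these objects are 1-based and inclusive.
#' @examples
#' rna_sequence("acgt", "q1")   # stored as "ACGU"
#' @export
rna_sequence <- function(residues, id = "seq") {
  if (inherits(residues, "rna_sequence")) return(residues)
  stopifnot(is.character(residues))
  if (length(residues) > 1) residues <- paste0(residues, collapse = "")
  if (length(residues) == 0) residues <- ""
  res <- normalize_residues(residues, id = id)
  structure(list(id = as.character(id), residues = res),
            class = "rna_sequence")
}

# T -> U, case fold, hard error on anything else (reports 1-based position)
normalize_residues <- function(x, id = "seq") {
  x <- toupper(x)
  x <- chartr("T", "U", x)
  bad <- regexpr("[^ACGU]", x)
  if (bad > 0) {
    stop(sprintf("illegal residue '%s' at position %d in sequence '%s'",
                 substr(x, bad, bad), bad, id), call. = FALSE)
  }
  x
}

#' @export
length.rna_sequence <- function(x) nchar(x$residues)

#' @export
print.rna_sequence <- function(x, ...) {
  n <- nchar(x$residues)
  shown <- if (n > 60) paste0(substr(x$residues, 1, 57), "...") else x$residues
  cat(sprintf("rna_sequence '%s' (%d nt)\n  %s\n", x$id, n, shown))
  invisible(x)
}

#' @export
as.character.rna_sequence <- function(x, ...) x$residues

# coerce character / rna_sequence uniformly
as_rna <- function(x, id = "seq") {
  if (inherits(x, "rna_sequence")) x else rna_sequence(x, id = id)
}

# integer codes 1..4 for A,C,G,U (0-length for empty sequence)
rna_codes <- function(x) {
  s <- as_rna(x)$residues
  if (nchar(s) == 0) return(integer(0))
  match(strsplit(s, "", fixed = TRUE)[[1]], c("A", "C", "G", "U"))
}

#' Read sequences from a FASTA file
#'
#' Records are normalized (upper case, `T` mapped to `U`); any other
#' character is an error naming the record and offending position.
#'
#' @param path path to a FASTA file.
#' @return list of [rna_sequence] objects, in file order (empty list for
#'   an empty file).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  out <- vector("list", length(set))
  nm <- names(set)
  for (i in seq_along(set)) {
    id <- sub("\\s.*$", "", nm[i])
    if (!nzchar(id)) id <- paste0("seq", i)
    out[[i]] <- rna_sequence(as.character(set[[i]]), id = id)
  }
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs list of [rna_sequence] (or character strings).
#' @param path output path.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (inherits(seqs, "rna_sequence")) seqs <- list(seqs)
  seqs <- lapply(seqs, as_rna)
  con <- file(path, "w")
  on.exit(close(con))
  for (sq in seqs) {
    writeLines(paste0(">", sq$id), con)
    s <- sq$residues
    if (nchar(s) == 0) next
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Reverse complement of an RNA sequence
#'
#' Used by the optional reverse-strand scanning mode.
#'
#' @param x [rna_sequence] or string.
#' @return [rna_sequence] with id suffixed `_rc`.
#' @export
reverse_complement <- function(x) {
  x <- as_rna(x)
  s <- chartr("ACGU", "UGCA", x$residues)
  s <- paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  rna_sequence(s, id = paste0(x$id, "_rc"))
}
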