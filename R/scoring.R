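RNA_ALPHABET <- c("A", "C", "G", "U")

# complementary pairs (Watson-Crick + wobble)
COMPLEMENTARY <- c("AU", "UA", "CG", "GC", "GU", "UG")

#' Scoring scheme for structural alignment
#'
#' Bundles the four ingredients of the score model: the character
#' similarity table `gamma(u1, u2)` (query character vs target
#' character), the base-pair similarity function
#' `delta(u1, u2, v1, v2)` (query pair `(u1, u2)` vs the two target
#' characters `(v1, v2)` they are aligned to), and the affine gap
#' penalties: a gap of length `L` costs `gap_open + gap_extend * L`.
#'
#' @param gamma 4x4 numeric matrix with dimnames `A, C, G, U`
#'   (rows: query character, columns: target character).
#' @param delta 4-dimensional `4 x 4 x 4 x 4` numeric array indexed
#'   `[u1, u2, v1, v2]`, or `NULL` for the default (see
#'   [default_scheme()]).
#' @param gap_open nonnegative gap opening penalty `h`.
#' @param gap_extend nonnegative gap extension penalty `s`.
#' @return object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(gamma = NULL, delta = NULL,
                           gap_open = 5, gap_extend = 0.1) {
  if (is.null(gamma)) gamma <- default_gamma()
  gamma <- as.matrix(gamma)
  stopifnot(identical(dim(gamma), c(4L, 4L)))
  if (is.null(dimnames(gamma))) dimnames(gamma) <- list(RNA_ALPHABET, RNA_ALPHABET)
  gamma <- gamma[RNA_ALPHABET, RNA_ALPHABET]
  delta_default <- is.null(delta)
  if (delta_default) delta <- default_delta(gamma)
  stopifnot(identical(dim(delta), c(4L, 4L, 4L, 4L)))
  dimnames(delta) <- list(RNA_ALPHABET, RNA_ALPHABET, RNA_ALPHABET, RNA_ALPHABET)
  stopifnot(is.numeric(gap_open), gap_open >= 0,
            is.numeric(gap_extend), gap_extend >= 0)
  structure(list(gamma = gamma, delta = delta,
                 gap_open = as.numeric(gap_open),
                 gap_extend = as.numeric(gap_extend),
                 delta_default = delta_default),
            class = "scoring_scheme")
}

default_gamma <- function() {
  g <- matrix(-1, 4, 4, dimnames = list(RNA_ALPHABET, RNA_ALPHABET))
  diag(g) <- 1
  g
}

# delta(u1,u2,v1,v2) = gamma(u1,v1) + gamma(u2,v2) + 2 if (v1,v2)
# complementary, else - 2: rewards conserved pairing and compensatory
# double substitutions over plain character similarity.
default_delta <- function(gamma = default_gamma()) {
  d <- array(0, c(4, 4, 4, 4))
  for (u1 in 1:4) for (u2 in 1:4) for (v1 in 1:4) for (v2 in 1:4) {
    comp <- paste0(RNA_ALPHABET[v1], RNA_ALPHABET[v2]) %in% COMPLEMENTARY
    d[u1, u2, v1, v2] <- gamma[u1, v1] + gamma[u2, v2] + if (comp) 2 else -2
  }
  d
}

#' Default scoring scheme
#'
#' `gamma` is +1 for a match and -1 for a mismatch; `delta` adds the two
#' character scores of the pair's endpoints plus a bonus of +2 when the
#' target characters are complementary (Watson-Crick or wobble) and -2
#' otherwise, so that a compensatory double mutation preserving pairing
#' still scores well.  Gap penalties default to `h = 5`, `s = 0.1`.
#'
#' @param gap_open,gap_extend affine gap penalties.
#' @return [scoring_scheme].
#' @export
default_scheme <- function(gap_open = 5, gap_extend = 0.1) {
  scoring_scheme(gap_open = gap_open, gap_extend = gap_extend)
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat(sprintf("scoring_scheme: h = %g, s = %g, delta = %s\n",
              x$gap_open, x$gap_extend,
              if (isTRUE(x$delta_default)) "default(compensatory)" else "dense table"))
  invisible(x)
}

# short digest used in provenance headers
scheme_digest <- function(scheme) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(list(scheme$gamma, scheme$delta, scheme$gap_open, scheme$gap_extend),
          tf, compress = FALSE)
  substr(unname(tools::md5sum(tf)), 1, 10)
}

gamma_of <- function(scheme, u, v) scheme$gamma[u, v]

#' Read a scoring configuration file
#'
#' JSON document with optional keys `gamma` (4x4, row-major with rows
#' named or in A,C,G,U order), `delta` (either the string `"default"` or
#' a dense 256-value array nested `[u1][u2][v1][v2]`), `gap_open` and
#' `gap_extend`.  Absent keys fall back to the default scheme.
#'
#' @param path JSON file path.
#' @return [scoring_scheme].
#' @export
read_scoring_config <- function(path) {
  if (!file.exists(path)) stop("scoring config not found: ", path, call. = FALSE)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  gamma <- if (!is.null(doc$gamma)) {
    matrix(as.numeric(unlist(doc$gamma)), 4, 4, byrow = TRUE,
           dimnames = list(RNA_ALPHABET, RNA_ALPHABET))
  } else NULL
  delta <- NULL
  if (!is.null(doc$delta) && !identical(doc$delta, "default")) {
    # nested lists [u1][u2][v1][v2]: unlist runs v2 fastest, u1 slowest
    delta <- aperm(array(as.numeric(unlist(doc$delta)), c(4, 4, 4, 4)), 4:1)
  }
  scoring_scheme(gamma = gamma, delta = delta,
                 gap_open = if (is.null(doc$gap_open)) 5 else doc$gap_open,
                 gap_extend = if (is.null(doc$gap_extend)) 0.1 else doc$gap_extend)
}

#' Write a scoring configuration file
#'
#' Inverse of [read_scoring_config()]; `write(read(x))` is semantically
#' lossless.
#'
#' @param scheme [scoring_scheme].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scoring_config <- function(scheme, path) {
  stopifnot(inherits(scheme, "scoring_scheme"))
  doc <- list(
    gamma = unname(apply(scheme$gamma, 1, function(r) as.numeric(r), simplify = FALSE)),
    delta = if (isTRUE(scheme$delta_default)) "default" else
      lapply(1:4, function(u1) lapply(1:4, function(u2)
        lapply(1:4, function(v1) as.numeric(scheme$delta[u1, u2, v1, ])))),
    gap_open = scheme$gap_open,
    gap_extend = scheme$gap_extend
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
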