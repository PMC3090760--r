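# synthetic families and decoy genomes emulating the scanning experiment

with_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

#' Random regular secondary structure
#'
#' Generates a pseudoknot-free structure by recursive construction:
#' position `l` is paired with probability `pair_prob` to a random
#' partner far enough away (`min_loop` unpaired positions inside a
#' hairpin), then the inside and the rest are generated recursively.
#' Non-crossing by construction.
#'
#' @param m sequence length.
#' @param pair_prob probability of opening a pair at each position.
#' @param min_loop minimum hairpin loop size (3 is the physical value
#'   for RNA; tests use smaller values to cover degenerate shapes).
#' @param seed optional seed for reproducibility.
#' @return [secondary_structure].
#' @export
random_regular_structure <- function(m, pair_prob = 0.3, min_loop = 3L,
                                     seed = NULL) {
  gen <- function() {
    pairs <- matrix(integer(0), ncol = 2)
    recurse <- function(l, r) {
      while (l <= r) {
        if (r - l >= min_loop + 1 && stats::runif(1) < pair_prob) {
          lo <- l + min_loop + 1L
          j <- lo + sample.int(r - lo + 1L, 1L) - 1L
          pairs <<- rbind(pairs, c(l, j))
          recurse(l + 1L, j - 1L)
          l <- j + 1L
        } else {
          l <- l + 1L
        }
      }
    }
    if (m >= 1) recurse(1L, as.integer(m))
    secondary_structure(pairs, m)
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Random RNA sequence compatible with a structure
#'
#' Unpaired positions are uniform over A, C, G, U; paired positions get
#' a random complementary pair (Watson-Crick or wobble).
#'
#' @param structure [secondary_structure].
#' @param seed optional seed.
#' @param id identifier.
#' @return [rna_sequence].
#' @export
random_compatible_sequence <- function(structure, seed = NULL, id = "member") {
  gen <- function() {
    m <- structure$seq_length
    ch <- sample(RNA_ALPHABET, m, replace = TRUE)
    p <- structure$pairs
    if (nrow(p)) for (r in seq_len(nrow(p))) {
      duo <- strsplit(sample(COMPLEMENTARY, 1), "")[[1]]
      ch[p[r, 1]] <- duo[1]; ch[p[r, 2]] <- duo[2]
    }
    rna_sequence(paste0(ch, collapse = ""), id = id)
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Mutate a family member
#'
#' Produces a diverged copy of a structured sequence: point
#' substitutions anywhere at rate `point_rate` (a substitution hitting a
#' paired position is applied as a compensatory double substitution,
#' replacing the pair with a random complementary pair, so the donor
#' structure stays interpretable), plus at most one insertion or
#' deletion of up to `loop_indel_max` nucleotides at an unpaired
#' (loop) position.
#'
#' @param seq [rna_sequence] or string.
#' @param structure [secondary_structure] of the donor.
#' @param point_rate substitution rate in `[0, 1]`.
#' @param loop_indel_max maximum indel length (0 disables indels).
#' @param seed optional seed.
#' @return [rna_sequence] (length may differ by the indel).
#' @export
mutate_member <- function(seq, structure, point_rate = 0.1,
                          loop_indel_max = 5L, seed = NULL) {
  seq <- as_rna(seq)
  st <- as_structure(structure, m = nchar(seq$residues))
  stopifnot(point_rate >= 0, point_rate <= 1)
  gen <- function() {
    ch <- strsplit(seq$residues, "", fixed = TRUE)[[1]]
    m <- length(ch)
    partner <- integer(m)
    if (nrow(st$pairs)) {
      partner[st$pairs[, 1]] <- st$pairs[, 2]
      partner[st$pairs[, 2]] <- st$pairs[, 1]
    }
    hit <- which(stats::runif(m) < point_rate)
    for (i in hit) {
      if (partner[i] > 0) {
        duo <- strsplit(sample(COMPLEMENTARY, 1), "")[[1]]
        a <- min(i, partner[i]); b <- max(i, partner[i])
        ch[a] <- duo[1]; ch[b] <- duo[2]
      } else {
        ch[i] <- sample(setdiff(RNA_ALPHABET, ch[i]), 1)
      }
    }
    if (loop_indel_max > 0) {
      loops <- which(partner == 0)
      if (length(loops)) {
        pos <- if (length(loops) == 1) loops else sample(loops, 1)
        len <- sample(seq_len(loop_indel_max), 1)
        if (stats::runif(1) < 0.5) {  # insertion after pos
          ins <- sample(RNA_ALPHABET, len, replace = TRUE)
          ch <- append(ch, ins, after = pos)
        } else {                      # deletion of unpaired run from pos
          del <- loops[loops >= pos]
          del <- del[seq_len(min(len, length(del)))]
          # only delete a contiguous unpaired run
          del <- del[del - pos == seq_along(del) - 1]
          if (length(del)) ch <- ch[-del]
        }
      }
    }
    rna_sequence(paste0(ch, collapse = ""), id = paste0(seq$id, "_mut"))
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Build a synthetic decoy genome with embedded members
#'
#' Emulates the scanning experiment: family member sequences are
#' embedded at random non-overlapping positions in an i.i.d. uniform
#' random background whose total length is `genome_length_factor` times
#' the total member length (members included), so background length is
#' `(factor - 1) x total`.
#'
#' @param members list of [rna_sequence] (or strings): the sequences to
#'   embed (at most 100 are used, sampled at random if more).
#' @param genome_length_factor genome length as a multiple of total
#'   member length (default 10).
#' @param seed random seed (required: fixtures are reproducible).
#' @param id genome identifier.
#' @return list: `genome` ([rna_sequence]), `truth` (data.frame with
#'   `member_id`, `start`, `end`, 1-based inclusive, non-overlapping,
#'   ordered by `start`).
#' @export
make_fixture <- function(members, genome_length_factor = 10, seed,
                         id = "decoy_genome") {
  stopifnot(length(members) >= 1, !missing(seed))
  members <- lapply(members, as_rna)
  with_seed(seed, {
    if (length(members) > 100) members <- sample(members, 100)
    mlens <- vapply(members, function(x) nchar(x$residues), integer(1))
    total <- sum(mlens)
    bg_len <- max(0L, as.integer(round((genome_length_factor - 1) * total)))
    if (bg_len < length(members) - 1L)
      stop("members cannot fit without overlap: background too short",
           call. = FALSE)
    bg <- sample(RNA_ALPHABET, bg_len, replace = TRUE)
    # cut the background into (#members + 1) segments at sorted random
    # cut points; members go between consecutive segments
    k <- length(members)
    cuts <- sort(sample.int(bg_len + 1L, k, replace = TRUE) - 1L)
    ord <- sample.int(k)   # embedding order is random too
    pieces <- character(2 * k + 1)
    truth <- data.frame(member_id = character(k), start = integer(k),
                        end = integer(k))
    pos <- 0L; prev <- 0L
    out <- character(0)
    for (i in seq_len(k)) {
      seg <- if (cuts[i] > prev) paste0(bg[(prev + 1):cuts[i]], collapse = "") else ""
      out <- c(out, seg)
      pos <- pos + nchar(seg)
      mem <- members[[ord[i]]]
      truth$member_id[i] <- mem$id
      truth$start[i] <- pos + 1L
      truth$end[i] <- pos + nchar(mem$residues)
      out <- c(out, mem$residues)
      pos <- pos + nchar(mem$residues)
      prev <- cuts[i]
    }
    if (bg_len > prev) out <- c(out, paste0(bg[(prev + 1):bg_len], collapse = ""))
    genome <- rna_sequence(paste0(out, collapse = ""), id = id)
    list(genome = genome, truth = truth)
  })
}

#' Generate a complete synthetic family fixture
#'
#' Convenience wrapper tying the pieces together: draws a random regular
#' structure and a compatible consensus sequence, derives `n_members`
#' mutated members ([mutate_member()]), and embeds them in a decoy
#' genome ([make_fixture()]).
#'
#' @param n_members number of embedded members.
#' @param member_length consensus length.
#' @param point_rate,loop_indel_max passed to [mutate_member()].
#' @param genome_length_factor passed to [make_fixture()].
#' @param pair_prob structure density, passed to
#'   [random_regular_structure()].
#' @param seed random seed (required).
#' @return list: `query` (consensus [rna_sequence]), `structure`,
#'   `members`, `genome`, `truth`.
#' @export
make_family_fixture <- function(n_members = 20, member_length = 40,
                                point_rate = 0.1, loop_indel_max = 5L,
                                genome_length_factor = 10,
                                pair_prob = 0.3, seed) {
  stopifnot(!missing(seed))
  with_seed(seed, {
    st <- random_regular_structure(member_length, pair_prob = pair_prob)
    query <- random_compatible_sequence(st, id = "consensus")
    members <- lapply(seq_len(n_members), function(i) {
      mem <- mutate_member(query, st, point_rate = point_rate,
                           loop_indel_max = loop_indel_max)
      mem$id <- sprintf("member_%02d", i)
      mem
    })
    fx <- make_fixture(members, genome_length_factor = genome_length_factor,
                       seed = sample.int(.Machine$integer.max, 1))
    c(list(query = query, structure = st, members = members), fx)
  })
}
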